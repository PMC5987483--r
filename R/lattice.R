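#' SF-6D lattice specification
#'
#' The SF-6D describes health on six dimensions (physical functioning, role
#' limitation, social functioning, bodily pain, mental health, vitality) with
#' 6, 4, 5, 6, 5 and 5 levels respectively, so that 18,000 distinct states are
#' definable, each named by a six-digit code from \code{"111111"} (full
#' health) to \code{"645655"} (the "pits", the worst state). Lower levels are
#' better health.
#'
#' @param level_counts integer vector of levels per dimension; the default is
#'   the SF-6D descriptive system.
#' @return An object of class \code{"sf6d_spec"}: a list with
#'   \code{level_counts}, dimension names, and the total state count.
#' @examples
#' sf6d_spec()$n_states  # 18000
#' @export
sf6d_spec <- function(level_counts = c(6L, 4L, 5L, 6L, 5L, 5L)) {
  level_counts <- as.integer(level_counts)
  if (length(level_counts) != 6L || any(level_counts < 1L))
    stop("level_counts must be six positive integers")
  if (any(level_counts > 9L))
    stop("level_counts above 9 cannot be written as single-digit codes")
  structure(
    list(level_counts = level_counts,
         dimensions = c("physical", "role", "social", "pain", "mental",
                        "vitality"),
         n_states = prod(level_counts)),
    class = "sf6d_spec")
}

#' @export
print.sf6d_spec <- function(x, ...) {
  cat("SF-6D-type lattice:", paste(x$level_counts, collapse = "x"),
      "levels =", x$n_states, "states\n")
  invisible(x)
}

#' Parse six-digit state codes
#'
#' @param code character vector of six-digit state codes.
#' @param spec an [sf6d_spec()].
#' @return An integer matrix with one row per code and one column per
#'   dimension (a row is a health state's level vector).
#' @examples
#' parse_state("645655")
#' @export
parse_state <- function(code, spec = sf6d_spec()) {
  code <- as.character(code)
  bad <- !grepl("^[0-9]{6}$", code)
  if (any(bad))
    stop("malformed state code(s): ", paste(code[bad], collapse = ", "),
         " (need exactly six digits)")
  m <- matrix(as.integer(unlist(strsplit(code, ""), use.names = FALSE)),
              ncol = 6L, byrow = TRUE)
  colnames(m) <- spec$dimensions
  for (d in 1:6) {
    out <- m[, d] < 1L | m[, d] > spec$level_counts[d]
    if (any(out))
      stop(sprintf(
        "level %d out of range 1..%d on dimension %d (%s) in state %s",
        m[which(out)[1], d], spec$level_counts[d], d, spec$dimensions[d],
        code[which(out)[1]]))
  }
  rownames(m) <- code
  m
}

#' Write level matrices back to six-digit codes
#'
#' @param levels integer matrix (rows = states, 6 columns) or a single
#'   length-6 level vector.
#' @return Character vector of codes; \code{state_code(parse_state(x))}
#'   round-trips.
#' @export
state_code <- function(levels) {
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  unname(apply(levels, 1L, paste0, collapse = ""))
}

#' Enumerate every state of a lattice
#'
#' Deterministic lexicographic order with dimension 1 slowest, so the default
#' lattice runs from "111111" to "645655"; this canonical order is what makes
#' covariance matrices and fixtures reproducible.
#'
#' @param spec an [sf6d_spec()].
#' @return Integer matrix of all \code{spec$n_states} level combinations,
#'   rownames set to the codes.
#' @export
enumerate_states <- function(spec = sf6d_spec()) {
  g <- expand.grid(rev(lapply(spec$level_counts, seq_len)),
                   KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g[, 6:1])
  dimnames(m) <- NULL
  m <- matrix(as.integer(m), ncol = 6L)
  colnames(m) <- spec$dimensions
  rownames(m) <- state_code(m)
  m
}

#' Adjacent states on the lattice
#'
#' Adjacency is a change of exactly one level in exactly one dimension
#' (Hamming-1 on the lattice), the only definition consistent with every
#' state having between 6 and 12 neighbours.
#'
#' @param state a length-6 level vector or a single six-digit code.
#' @param spec an [sf6d_spec()].
#' @return Integer matrix of neighbouring states (6 to 12 rows).
#' @export
neighbors <- function(state, spec = sf6d_spec()) {
  if (is.character(state)) state <- parse_state(state, spec)[1L, ]
  state <- as.integer(state)
  out <- list()
  for (d in 1:6) {
    for (step in c(-1L, 1L)) {
      lev <- state[d] + step
      if (lev >= 1L && lev <= spec$level_counts[d]) {
        nb <- state
        nb[d] <- lev
        out[[length(out) + 1L]] <- nb
      }
    }
  }
  m <- do.call(rbind, out)
  colnames(m) <- spec$dimensions
  rownames(m) <- state_code(m)
  m
}

#' Number of adjacent states, for one or many states at once
#'
#' Closed form: each dimension contributes 2 unless the state sits at one of
#' that dimension's endpoints (then 1), so the degree lies in [6, 12].
#'
#' @param levels integer matrix of states (rows).
#' @param spec an [sf6d_spec()].
#' @return Integer vector of adjacency degrees.
#' @export
adjacency_degree <- function(levels, spec = sf6d_spec()) {
  if (is.null(dim(levels))) levels <- matrix(levels, nrow = 1L)
  deg <- integer(nrow(levels))
  for (d in 1:6)
    deg <- deg + (levels[, d] > 1L) + (levels[, d] < spec$level_counts[d])
  deg
}

#' Dominance between health states
#'
#' State \code{a} dominates \code{b} when it is at least as good on every
#' dimension (lower level = better health) and strictly better on at least
#' one: a strict partial order used by the monotonicity audit.
#'
#' @param a,b length-6 level vectors or six-digit codes.
#' @param spec an [sf6d_spec()].
#' @return Logical scalar.
#' @export
dominates <- function(a, b, spec = sf6d_spec()) {
  if (is.character(a)) a <- parse_state(a, spec)[1L, ]
  if (is.character(b)) b <- parse_state(b, spec)[1L, ]
  all(a <= b) && any(a < b)
}

#' Sample distinct states uniformly without replacement
#'
#' @param spec an [sf6d_spec()].
#' @param n number of states to draw (at most \code{spec$n_states}).
#' @param seed optional integer seed for reproducibility.
#' @return Integer matrix of \code{n} distinct states.
#' @export
sample_states <- function(spec = sf6d_spec(), n, seed = NULL) {
  n <- as.integer(n)
  if (n > spec$n_states)
    stop("cannot sample ", n, " distinct states from a lattice of ",
         spec$n_states)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  all_states <- enumerate_states(spec)
  all_states[sample.int(spec$n_states, n), , drop = FALSE]
}

# restore (or clear) .Random.seed after a locally seeded computation
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
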