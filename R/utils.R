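# Internal helpers shared across modules.

#' Derive a child seed from a master seed and a counter
#'
#' Every repeated procedure (CV repetitions, PRESS sub-samples, fold-plan
#' repetitions) derives its own RNG seed from the master seed by counter, so
#' that runs are reproducible and repetitions are independent of how many of
#' them precede a given one.
#'
#' @param seed master seed (integer).
#' @param counter repetition counter (positive integer).
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
child_seed <- function(seed, counter) {
  # affine hash mod a large prime below 2^31; keeps seeds in integer range
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %% 2147483629)
}

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Mode with ties broken toward the smallest value.
mode_smallest <- function(x) {
  tab <- table(x)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  min(winners)
}

# Partition indices 1..n into k validation folds (sizes differing by at most
# one). When `groups` is given, whole groups are assigned to folds so that no
# group straddles a fold boundary.
make_folds <- function(n, k, seed, groups = NULL) {
  stopifnot(k >= 2)
  with_seed(seed, {
    if (is.null(groups)) {
      idx <- sample.int(n)
      fold_of <- rep(seq_len(k), length.out = n)
      lapply(seq_len(k), function(f) sort(idx[fold_of == f]))
    } else {
      stopifnot(length(groups) == n)
      ug <- unique(groups)
      if (k > length(ug)) {
        stop("k_folds (", k, ") exceeds the number of distinct groups (",
             length(ug), ")")
      }
      ug <- sample(ug)
      gfold <- rep(seq_len(k), length.out = length(ug))
      lapply(seq_len(k), function(f) which(groups %in% ug[gfold == f]))
    }
  })
}

# All permutations of 1..n as a list (n <= 8 guard; used by exact Mantel).
all_permutations <- function(n) {
  stopifnot(n <= 8)
  if (n == 1) return(list(1L))
  out <- vector("list", factorial(n))
  i <- 0L
  rec <- function(head, rest) {
    if (length(rest) == 0) {
      i <<- i + 1L
      out[[i]] <<- head
      return(invisible())
    }
    for (j in seq_along(rest)) rec(c(head, rest[j]), rest[-j])
  }
  rec(integer(0), seq_len(n))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
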