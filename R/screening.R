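#' Pairwise Pearson correlation matrix of a factor table
#'
#' Only complete rows enter the computation. Zero-variance factors cannot be
#' correlated; they are dropped with a warning and recorded in the
#' `dropped_zero_variance` attribute (their columns never reach the
#' screening loop). Categorical factors enter as their integer codes.
#'
#' @param factor_matrix data frame or matrix of factor values; an `id`
#'   column, if present, is ignored.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(factor_matrix) {
  m <- factor_matrix
  if (is.data.frame(m)) m <- m[setdiff(names(m), "id")]
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("pearson_matrix: need at least 3 complete rows")
  v <- apply(m, 2L, var)
  zero <- colnames(m)[v == 0]
  if (length(zero)) {
    warning("pearson_matrix: zero-variance factor(s) dropped: ",
            paste(zero, collapse = ", "))
    m <- m[, v > 0, drop = FALSE]
  }
  if (ncol(m) < 1) stop("pearson_matrix: no factor with nonzero variance")
  r <- cor(m)
  structure(r, dropped_zero_variance = zero)
}

#' Iteratively screen factors to a pairwise correlation ceiling
#'
#' Greedy worst-pair-first removal: repeatedly find the off-diagonal pair
#' with the largest absolute correlation; if it exceeds `threshold`, drop the
#' lower-priority member and recompute on the survivors; stop once all
#' retained pairs satisfy `|r| <= threshold`.
#'
#' The default priority keeps, within the worst pair, the factor with the
#' smaller mean absolute correlation to all other current factors (the least
#' redundant one), ties broken lexicographically. A user-supplied `priority`
#' character vector (most important first) overrides this and stands in for
#' expert judgement of biological relevance.
#'
#' @param factor_matrix as for [pearson_matrix()].
#' @param threshold retained pairs must have `|r|` at or below this (default
#'   0.8).
#' @param priority optional character vector of factor names, most important
#'   first; factors not listed rank below all listed ones.
#' @return A `screening_report`: list with the full initial correlation
#'   matrix, `retained` names, `dropped` data frame (`name`, `round`,
#'   `partner`, `r`), `rounds` and `threshold`.
#' @export
iterative_screen <- function(factor_matrix, threshold = 0.8, priority = NULL) {
  r_full <- pearson_matrix(factor_matrix)
  current <- colnames(r_full)
  r <- r_full
  dropped <- data.frame(name = character(), round = integer(),
                        partner = character(), r = numeric(),
                        stringsAsFactors = FALSE)
  zv <- attr(r_full, "dropped_zero_variance")
  round_i <- 0L
  repeat {
    if (length(current) == 0L)
      stop("iterative_screen: all factors dropped; threshold unattainable")
    if (length(current) == 1L) break
    a <- abs(r); diag(a) <- 0
    worst <- which(a == max(a), arr.ind = TRUE)[1L, ]
    if (a[worst[1], worst[2]] <= threshold) break
    round_i <- round_i + 1L
    pair <- current[c(worst[1], worst[2])]
    drop_name <- pick_drop(pair, r, priority)
    keep_name <- setdiff(pair, drop_name)
    dropped <- rbind(dropped, data.frame(
      name = drop_name, round = round_i, partner = keep_name,
      r = r[pair[1], pair[2]], stringsAsFactors = FALSE))
    current <- setdiff(current, drop_name)
    r <- r[current, current, drop = FALSE]
  }
  structure(list(correlations = r_full, retained = current,
                 dropped = dropped, rounds = round_i,
                 threshold = threshold, zero_variance = zv),
            class = "screening_report")
}

# which member of the worst pair to drop
pick_drop <- function(pair, r, priority) {
  if (!is.null(priority)) {
    rank_of <- function(nm) {
      i <- match(nm, priority)
      if (is.na(i)) length(priority) + 1L else i
    }
    ranks <- vapply(pair, rank_of, 0L)
    if (ranks[1] != ranks[2]) return(pair[which.max(ranks)])
  }
  # keep the least redundant member: smaller mean |r| to the others
  mean_abs <- vapply(pair, function(nm) {
    others <- setdiff(colnames(r), nm)
    if (!length(others)) return(0)
    mean(abs(r[nm, others]))
  }, 0)
  if (mean_abs[1] != mean_abs[2]) pair[which.max(mean_abs)]
  else sort(pair)[2L]  # lexicographic tie-break: keep the first
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("screening_report: %d retained, %d dropped in %d round(s), threshold %.2f\n",
              length(x$retained), nrow(x$dropped), x$rounds, x$threshold))
  if (nrow(x$dropped)) {
    cat("dropped:\n")
    print(x$dropped, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a screening report to delimited text + JSON
#' @param report a `screening_report`.
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_screening_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "screening_retained.csv")
  write.csv(data.frame(factor = report$retained), p1, row.names = FALSE)
  p2 <- file.path(dir, "screening_dropped.csv")
  write.csv(report$dropped, p2, row.names = FALSE)
  p3 <- file.path(dir, "screening.json")
  jsonlite::write_json(
    list(threshold = report$threshold, rounds = report$rounds,
         retained = report$retained, dropped = report$dropped),
    p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
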