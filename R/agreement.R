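# Inter-rater agreement: observed agreement, Cohen's kappa, weighted kappa.
#
# For two raters with ratings on k ordered categories and weight matrix w
# (w[i,i] = 1), the weighted observed agreement is the mean weight of the
# observed pairs, the chance agreement is sum_ij w[i,j] p_a(i) p_b(j) from
# the raters' marginals, and kappa = (po - pe) / (1 - pe). Weights:
#   none       w[i,j] = 1{i == j}            (ordinary Cohen's kappa)
#   linear     w[i,j] = 1 - |i - j| / (k-1)
#   quadratic  w[i,j] = 1 - (i - j)^2 / (k-1)^2
# With more than two raters, statistics are averaged over all rater pairs
# (the within- and between-observer designs this supports are pairwise).

weight_matrix <- function(k, weighting) {
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(weighting,
         none = (d == 0) * 1,
         linear = if (k == 1L) matrix(1, 1, 1) else 1 - d / (k - 1),
         quadratic = if (k == 1L) matrix(1, 1, 1) else 1 - (d / (k - 1))^2)
}

pair_kappa <- function(a, b, categories, weighting) {
  k <- length(categories)
  ia <- match(a, categories); ib <- match(b, categories)
  n <- length(a)
  w <- weight_matrix(k, weighting)
  po <- mean(w[cbind(ia, ib)])
  pa <- tabulate(ia, k) / n
  pb <- tabulate(ib, k) / n
  pe <- sum(w * outer(pa, pb))
  if (abs(1 - pe) < 1e-12) {
    return(list(po = po, kappa = NA_real_, se = NA_real_, degenerate = TRUE))
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / n) / (1 - pe)  # large-sample, unweighted form
  list(po = po, kappa = kappa, se = se, degenerate = FALSE)
}

#' Inter-rater agreement statistics
#'
#' Computes observed agreement, Cohen's kappa and weighted kappa for two or
#' more raters scoring the same items on a shared ordinal scale (e.g. MNCD
#' stages 1..5, or a 0/1 sub-axis flag). With more than two raters every
#' statistic is the average over all rater pairs.
#'
#' When the ratings are degenerate (every rater uses a single identical
#' category) chance agreement is 1 and kappa is undefined; it is reported as
#' `NA` with a note, while observed agreement is still returned.
#'
#' @param ratings a raters x items matrix (or data frame) of ratings; at
#'   least 2 rows (raters) and 1 column (items).
#' @param weighting `"none"` (default; ordinary Cohen's kappa), `"linear"`
#'   or `"quadratic"` disagreement weights for the weighted kappa.
#' @param categories the ordered category set defining distances for the
#'   weights; defaults to the sorted unique observed ratings. Supply the
#'   full scale (e.g. `1:5`) when not all categories occur.
#' @return An object of class `mncd_agreement`: `observed_agreement`
#'   (exact-match fraction, pairwise-averaged), `cohen_kappa` (unweighted),
#'   `weighted_kappa` (under `weighting`; equals `cohen_kappa` when
#'   `weighting = "none"`), `kappa_se` (large-sample standard error,
#'   pairwise-averaged; reported, not used for gating), `per_item`
#'   (per-item fraction of agreeing rater pairs), `n_raters`, `n_items`,
#'   `weighting`, `notes`.
#' @examples
#' r <- rbind(raterA = c(1, 2, 3, 4, 5), raterB = c(1, 2, 3, 4, 5))
#' agreement(r, categories = 1:5)$cohen_kappa  # 1
#' @export
agreement <- function(ratings, weighting = c("none", "linear", "quadratic"),
                      categories = NULL) {
  weighting <- match.arg(weighting)
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L) stop("need at least 2 raters (rows)", call. = FALSE)
  if (ncol(ratings) < 1L) stop("need at least 1 item (column)", call. = FALSE)
  if (anyNA(ratings)) stop("ratings must not contain NA", call. = FALSE)
  if (is.null(categories)) categories <- sort(unique(as.vector(ratings)))
  if (!all(ratings %in% categories)) {
    stop("ratings contain values outside `categories`", call. = FALSE)
  }
  pairs <- utils::combn(nrow(ratings), 2, simplify = FALSE)
  plain <- lapply(pairs, function(p)
    pair_kappa(ratings[p[1], ], ratings[p[2], ], categories, "none"))
  weighted <- if (weighting == "none") plain else lapply(pairs, function(p)
    pair_kappa(ratings[p[1], ], ratings[p[2], ], categories, weighting))

  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else
    mean(x, na.rm = TRUE)
  notes <- character()
  if (any(vapply(plain, `[[`, logical(1), "degenerate"))) {
    notes <- c(notes, paste("kappa undefined for at least one rater pair:",
                            "chance agreement is 1 (degenerate ratings)"))
  }
  per_item <- vapply(seq_len(ncol(ratings)), function(j) {
    mean(vapply(pairs, function(p)
      ratings[p[1], j] == ratings[p[2], j], logical(1)))
  }, numeric(1))
  names(per_item) <- colnames(ratings)

  structure(list(
    observed_agreement = mean(vapply(plain, `[[`, numeric(1), "po")),
    cohen_kappa = mean_or_na(vapply(plain, `[[`, numeric(1), "kappa")),
    weighted_kappa = mean_or_na(vapply(weighted, `[[`, numeric(1), "kappa")),
    kappa_se = mean_or_na(vapply(plain, `[[`, numeric(1), "se")),
    per_item = per_item,
    n_raters = nrow(ratings), n_items = ncol(ratings),
    weighting = weighting, notes = notes
  ), class = "mncd_agreement")
}

#' @export
print.mncd_agreement <- function(x, ...) {
  cat(sprintf("<MNCD agreement> %d raters, %d items\n",
              x$n_raters, x$n_items))
  cat(sprintf("  observed agreement: %.4f\n", x$observed_agreement))
  cat(sprintf("  Cohen's kappa:      %s (SE %s)\n",
              format(round(x$cohen_kappa, 4)),
              format(signif(x$kappa_se, 3))))
  if (x$weighting != "none") {
    cat(sprintf("  weighted kappa (%s): %s\n", x$weighting,
                format(round(x$weighted_kappa, 4))))
  }
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Read a long-format ratings table
#'
#' Reads a CSV with columns `item_id`, `rater_id`, `rating` and pivots it
#' to the raters x items matrix expected by [agreement()]. Every rater must
#' rate every item exactly once.
#'
#' @param path CSV file.
#' @return A raters x items numeric matrix with dimnames.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "rater_id", "rating")
  if (!all(need %in% names(df))) {
    stop(paste("ratings file must have columns:", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  raters <- unique(df$rater_id); items <- unique(df$item_id)
  m <- matrix(NA_real_, length(raters), length(items),
              dimnames = list(raters, items))
  idx <- cbind(match(df$rater_id, raters), match(df$item_id, items))
  if (anyDuplicated(idx)) {
    stop("duplicate (rater_id, item_id) rating", call. = FALSE)
  }
  m[idx] <- df$rating
  if (anyNA(m)) {
    stop("incomplete ratings: every rater must rate every item",
         call. = FALSE)
  }
  m
}

#' Per-component agreement between two raters' cohorts
#'
#' Given two cohorts holding the same visits rated by two raters, returns
#' the observed agreement for each sub-axis flag, cognition, dependency and
#' the derived stage — a per-axis/per-sub-axis view of where raters
#' disagree. Rows are matched by `(patient_id, years_from_onset)`.
#'
#' @param x,y `mncd_cohort` tables of the same visits.
#' @return Named numeric vector of observed-agreement proportions.
#' @export
rater_component_agreement <- function(x, y) {
  x <- stage_cohort(x); y <- stage_cohort(y)
  kx <- paste(x$patient_id, x$years_from_onset, sep = "\r")
  ky <- paste(y$patient_id, y$years_from_onset, sep = "\r")
  if (nrow(x) != nrow(y) || !setequal(kx, ky)) {
    stop("the two cohorts must contain the same (patient, time) visits",
         call. = FALSE)
  }
  y <- y[match(kx, ky), , drop = FALSE]
  cols <- c(RECORD_COLUMNS, "stage")
  vapply(cols, function(nm) mean(x[[nm]] == y[[nm]]), numeric(1))
}
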