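#' Z-score feature columns
#'
#' Standardizes each selected feature to mean 0 and sd 1 (sample sd, n-1
#' denominator) before distance computation, because the selected features
#' live on very different scales (SUV, cc, unitless texture indices).
#' Constant columns carry no distance information and are dropped with a
#' warning.
#'
#' @param features data.frame or matrix of features.
#' @param feature_names columns to standardize (default: all).
#' @return Numeric matrix of standardized columns.
#' @export
zscore_features <- function(features, feature_names = colnames(features)) {
  x <- as.matrix(as.data.frame(features)[, feature_names, drop = FALSE])
  if (nrow(x) < 2) stop("need at least 2 patients to standardize")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  scale(x)[, , drop = FALSE]
}

#' Hierarchical prognostic grouping
#'
#' Agglomerative clustering of the standardized feature rows with Euclidean
#' distance and complete linkage, cut into exactly `k` groups. Groups are
#' renumbered by increasing group mean of the first feature column, so
#' labels are deterministic and independent of the dendrogram's internal
#' ordering.
#'
#' @param z standardized feature matrix from [zscore_features()].
#' @param k number of groups (default 5).
#' @return An object of class `cluster_result`: `labels` (1..k per row),
#'   `tree` (the `hclust` object), `k`.
#' @export
hierarchical_groups <- function(z, k = 5L) {
  n <- nrow(z)
  if (n < k) stop("cannot cut ", n, " patients into ", k, " groups")
  tree <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "complete")
  raw <- stats::cutree(tree, k = k)
  means <- tapply(z[, 1], raw, mean)
  relabel <- match(raw, as.integer(names(sort(means))))
  structure(list(labels = relabel, tree = tree, k = as.integer(k)),
            class = "cluster_result")
}

# Half-up integer rounding (2.5 -> 3), the convention used for the printed
# group percentages.
round_half_up <- function(x) floor(x + 0.5)

#' Per-group outcome summary
#'
#' Summarizes each prognostic group in the style of a clinical outcome
#' table: group size, refractory count and integer percent of the group,
#' and deaths from Hodgkin lymphoma among the group's refractory cases with
#' the integer percent of those refractory cases (0 when the group has no
#' refractory case). Percentages are rounded half-up.
#'
#' @param labels group labels 1..k per patient.
#' @param outcomes data.frame with logical `refractory` and `death_from_hl`
#'   aligned with `labels`.
#' @return data.frame with one row per group: `group`, `n`, `refractory_n`,
#'   `refractory_pct`, `deaths_n`, `death_pct`.
#' @export
summarize_groups <- function(labels, outcomes) {
  stopifnot(length(labels) == nrow(outcomes))
  groups <- sort(unique(labels))
  rows <- lapply(groups, function(g) {
    in_g <- labels == g
    n <- sum(in_g)
    refr_n <- sum(outcomes$refractory[in_g])
    deaths <- sum(outcomes$refractory[in_g] & outcomes$death_from_hl[in_g])
    data.frame(group = g, n = n,
               refractory_n = refr_n,
               refractory_pct = round_half_up(100 * refr_n / n),
               deaths_n = deaths,
               death_pct = if (refr_n > 0)
                 round_half_up(100 * deaths / refr_n) else 0)
  })
  do.call(rbind, rows)
}
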