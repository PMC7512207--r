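shannon_entropy <- function(codes) {
  p <- table(codes) / length(codes)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Symmetrical uncertainty between two discrete columns
#'
#' `SU(a, b) = 2 * [H(a) - H(a|b)] / [H(a) + H(b)]`, with Shannon entropies
#' from empirical frequencies. Equals 1 when either column fully determines
#' the other and 0 when they are independent; defined as 0 when both
#' columns are constant.
#'
#' @param a,b Equal-length vectors of discrete values (factors, integers or
#'   characters).
#' @return Value in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(a, b) {
  if (length(a) != length(b)) stopf("columns must have equal length")
  ha <- shannon_entropy(a)
  hb <- shannon_entropy(b)
  if (ha + hb == 0) return(0)
  hab <- shannon_entropy(paste(a, b, sep = "\r"))
  su <- 2 * (ha + hb - hab) / (ha + hb)
  min(1, max(0, su))
}

# Fayyad-Irani entropy-minimization discretization with the MDL stopping
# rule. Returns cut points (possibly none).
mdlp_cuts <- function(x, y) {
  recurse <- function(xs, ys) {
    n <- length(xs)
    if (n < 4) return(numeric(0))
    base_ent <- shannon_entropy(ys)
    k <- length(unique(ys))
    if (k < 2) return(numeric(0))
    # candidate boundaries: midpoints between adjacent distinct values
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) return(numeric(0))
    best <- NULL; best_e <- Inf
    for (i in distinct) {
      yl <- ys[1:i]; yr <- ys[(i + 1):n]
      e <- (i / n) * shannon_entropy(yl) + ((n - i) / n) * shannon_entropy(yr)
      if (e < best_e) { best_e <- e; best <- i }
    }
    gain <- base_ent - best_e
    yl <- ys[1:best]; yr <- ys[(best + 1):n]
    k1 <- length(unique(yl)); k2 <- length(unique(yr))
    delta <- log2(3^k - 2) -
      (k * base_ent - k1 * shannon_entropy(yl) - k2 * shannon_entropy(yr))
    if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
    cut <- (xs[best] + xs[best + 1]) / 2
    c(recurse(xs[1:best], yl), cut, recurse(xs[(best + 1):n], yr))
  }
  o <- order(x)
  sort(recurse(x[o], y[o]))
}

#' Supervised discretization of a continuous column
#'
#' Entropy-minimization binning with the Fayyad-Irani MDL stopping rule,
#' computed against the class labels. A column where no cut passes the MDL
#' test collapses to a single bin (and thus has zero symmetrical
#' uncertainty with everything).
#'
#' @param column Continuous values.
#' @param labels Class labels, same length.
#' @return Integer bin codes with the cut points as attribute `"cuts"`.
#' @export
discretize <- function(column, labels) {
  if (length(column) != length(labels)) stopf("column/labels length mismatch")
  if (length(column) < 2) stopf("need at least 2 rows")
  cuts <- mdlp_cuts(column, as.character(labels))
  codes <- findInterval(column, cuts) + 1L
  attr(codes, "cuts") <- cuts
  codes
}

#' Fast correlation-based filter feature selection
#'
#' Two stages on the (training) feature table: each feature is discretized
#' against the group label and ranked by its symmetrical uncertainty with
#' the label (descending; ties broken by feature name); then the ranking is
#' walked from the top and every lower-ranked feature `Xj` with
#' `SU(Xi, Xj) >= SU(Xj, Y)` for a surviving higher-ranked `Xi` is
#' discarded and skipped in later comparisons. Features with zero relevance
#' (`SU = 0`, single-bin discretization) never enter the redundancy walk.
#'
#' @param table Feature table (training rows) with a `group` column.
#' @param feature_cols Feature column names (default the 14 standard ones).
#' @param label_col Label column name.
#' @return An object of class `"fcbf_selection"`: `ranked` (name + SU with
#'   the label), `selected` (survivors in rank order), `discarded`
#'   (feature, dominating feature) and `irrelevant` (SU = 0 features).
#' @export
fcbf <- function(table, feature_cols = feature_names(), label_col = "group") {
  if (!nrow(table)) stopf("empty training table")
  missing_cols <- setdiff(c(feature_cols, label_col), names(table))
  if (length(missing_cols))
    stopf("missing columns: %s", paste(missing_cols, collapse = ", "))
  y <- as.character(table[[label_col]])
  codes <- lapply(feature_cols, function(f) discretize(table[[f]], y))
  names(codes) <- feature_cols
  su_y <- vapply(feature_cols, function(f) symmetrical_uncertainty(codes[[f]], y), 0)
  ord <- order(-su_y, feature_cols)
  ranked <- data.frame(feature = feature_cols[ord], su = unname(su_y[ord]),
                       stringsAsFactors = FALSE)
  relevant <- ranked$feature[ranked$su > 0]
  irrelevant <- ranked$feature[ranked$su <= 0]
  status <- stats::setNames(rep("active", length(relevant)), relevant)
  dominator <- character(0)
  for (i in seq_along(relevant)) {
    xi <- relevant[i]
    if (status[xi] != "active") next
    if (i < length(relevant)) {
      for (xj in relevant[(i + 1):length(relevant)]) {
        if (status[xj] != "active") next
        if (symmetrical_uncertainty(codes[[xi]], codes[[xj]]) >= su_y[xj]) {
          status[xj] <- "discarded"
          dominator[xj] <- xi
        }
      }
    }
  }
  selected <- relevant[status[relevant] == "active"]
  discarded <- data.frame(feature = names(dominator),
                          dominated_by = unname(dominator),
                          stringsAsFactors = FALSE, row.names = NULL)
  structure(list(ranked = ranked, selected = selected, discarded = discarded,
                 irrelevant = irrelevant),
            class = "fcbf_selection")
}

#' @export
print.fcbf_selection <- function(x, ...) {
  cat("<fcbf_selection>\n  selected:", paste(x$selected, collapse = ", "), "\n")
  if (nrow(x$discarded))
    cat("  discarded:",
        paste(sprintf("%s (by %s)", x$discarded$feature, x$discarded$dominated_by),
              collapse = ", "), "\n")
  if (length(x$irrelevant))
    cat("  irrelevant (SU = 0):", paste(x$irrelevant, collapse = ", "), "\n")
  invisible(x)
}
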