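# Frequency-weighted ACR TI-RADS feature scoring of heat-map hot versus
# inactivated sub-nodular regions.
#
# Only the attributes that can be rated on sub-nodular components are scored:
# echogenicity, composition and echogenic foci. Shape and margin are
# whole-nodule attributes and are excluded; relative localization (on/off
# the nodule margin) is tabulated but carries no risk points.

tirads_attributes <- list(
  echogenicity = c("very hypoechoic", "hypoechoic", "isoechoic"),
  composition = c("solid"),
  foci = c("macro-calcification", "punctate calcification", "none")
)

#' ACR TI-RADS risk points for sub-nodular features
#'
#' The fixed published point values, versioned here rather than recomputed:
#' very hypoechoic 3, hypoechoic 2, isoechoic 1 (echogenicity); solid 2
#' (composition); punctate calcification 3, macro-calcification 1, none 0
#' (echogenic foci). Localization carries no points.
#'
#' @return Named numeric vector of class `risk_point_map`.
#' @export
risk_point_map <- function() {
  structure(c("very hypoechoic" = 3, "hypoechoic" = 2, "isoechoic" = 1,
              "solid" = 2,
              "punctate calcification" = 3, "macro-calcification" = 1,
              "none" = 0),
            class = "risk_point_map", version = "ACR TI-RADS 2017")
}

#' Build a feature frequency table
#'
#' @param counts Data frame with columns `attribute` (one of `echogenicity`,
#'   `composition`, `foci`, `localization`), `category` and `count`.
#' @param region_class `"hot"` or `"inactivated"`.
#' @param n_nodules Total number of rated nodules.
#' @return Object of class `feature_frequency_table` with per-category
#'   probabilities (`count / n_nodules`).
#' @export
feature_frequency_table <- function(counts, region_class, n_nodules) {
  stopifnot(all(c("attribute", "category", "count") %in% names(counts)),
            n_nodules > 0)
  region_class <- match.arg(region_class, c("hot", "inactivated"))
  counts$probability <- counts$count / n_nodules
  scoreable <- counts$attribute %in% names(tirads_attributes)
  for (attr in names(tirads_attributes)) {
    bad <- counts$attribute == attr &
      !(counts$category %in% tirads_attributes[[attr]])
    if (any(bad)) {
      stop(sprintf("unknown %s category: %s", attr,
                   paste(counts$category[bad], collapse = ", ")), call. = FALSE)
    }
    p_sum <- sum(counts$probability[counts$attribute == attr])
    if (p_sum > 1 + 1e-9) {
      stop(sprintf("probabilities for %s exceed 1", attr), call. = FALSE)
    }
  }
  structure(list(table = counts[order(match(counts$attribute,
                                            c("localization",
                                              names(tirads_attributes)))), ],
                 region_class = region_class,
                 n_nodules = as.integer(n_nodules),
                 scoreable = scoreable),
            class = "feature_frequency_table")
}

#' @export
print.feature_frequency_table <- function(x, ...) {
  cat(sprintf("<feature_frequency_table> %s regions, %d nodules\n",
              x$region_class, x$n_nodules))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Frequency-weighted ACR TI-RADS scores
#'
#' Each scoreable category's probability of occurrence is multiplied by its
#' ACR TI-RADS risk points; the summed score adds the echogenicity,
#' composition and echogenic-foci contributions. Localization rows pass
#' through unscored.
#'
#' @param table A [feature_frequency_table()].
#' @param points A [risk_point_map()].
#' @return List with `per_category` (data frame adding a `weighted_score`
#'   column) and `total` (the summed score).
#' @export
weighted_scores <- function(table, points = risk_point_map()) {
  stopifnot(inherits(table, "feature_frequency_table"))
  tab <- table$table
  scoreable <- tab$attribute %in% names(tirads_attributes)
  unknown <- scoreable & !(tab$category %in% names(points))
  if (any(unknown)) {
    stop(sprintf("no risk points defined for category: %s",
                 paste(tab$category[unknown], collapse = ", ")), call. = FALSE)
  }
  ws <- rep(NA_real_, nrow(tab))
  ws[scoreable] <- tab$probability[scoreable] *
    unname(points[tab$category[scoreable]])
  tab$weighted_score <- ws
  list(per_category = tab, total = sum(ws[scoreable]))
}

#' Tabulate frequencies from per-nodule ratings
#'
#' @param ratings Data frame with one row per nodule and region class:
#'   columns `region_class`, `echogenicity`, `composition`, `foci`, and
#'   optionally `localization` (`"on margin"` / `"not on margin"`). Columns
#'   for whole-nodule attributes (`shape`, `margin`) are ignored with a
#'   notice, since they cannot be rated on sub-nodular components.
#' @return Named list of [feature_frequency_table()] objects, one per region
#'   class present in `ratings`.
#' @export
tabulate_from_ratings <- function(ratings) {
  ratings <- as.data.frame(ratings)
  need <- c("region_class", names(tirads_attributes))
  miss <- setdiff(need, names(ratings))
  if (length(miss)) {
    stop(sprintf("ratings are missing required columns: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  dropped <- intersect(c("shape", "margin"), names(ratings))
  if (length(dropped)) {
    message("ignoring whole-nodule attributes: ", paste(dropped, collapse = ", "))
  }
  for (attr in names(tirads_attributes)) {
    if (anyNA(ratings[[attr]]) || any(ratings[[attr]] == "")) {
      stop(sprintf("missing %s rating", attr), call. = FALSE)
    }
  }
  out <- lapply(split(ratings, ratings$region_class), function(df) {
    n <- nrow(df)
    rows <- list()
    if ("localization" %in% names(df)) {
      for (cat in c("on margin", "not on margin")) {
        rows[[length(rows) + 1L]] <- data.frame(
          attribute = "localization", category = cat,
          count = sum(df$localization == cat))
      }
    }
    for (attr in names(tirads_attributes)) {
      for (cat in tirads_attributes[[attr]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          attribute = attr, category = cat, count = sum(df[[attr]] == cat))
      }
    }
    feature_frequency_table(do.call(rbind, rows),
                            region_class = df$region_class[1],
                            n_nodules = n)
  })
  out
}

#' Bundled reader-study frequency table
#'
#' Loads the frequency columns of the packaged radiologist reader study of
#' heat-map hot versus inactivated regions in 100 malignant nodules
#' (`inst/extdata/reader_study_frequencies.csv`).
#'
#' @param region_class `"hot"` or `"inactivated"`.
#' @return A [feature_frequency_table()].
#' @export
reference_frequency_table <- function(region_class = c("hot", "inactivated")) {
  region_class <- match.arg(region_class)
  path <- system.file("extdata", "reader_study_frequencies.csv",
                      package = "camsens", mustWork = TRUE)
  all <- utils::read.csv(path, stringsAsFactors = FALSE)
  sub <- all[all$region_class == region_class, ]
  feature_frequency_table(sub[, c("attribute", "category", "count")],
                          region_class = region_class,
                          n_nodules = sub$n_nodules[1])
}
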