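#' Read a per-slice measurement table
#'
#' CSV dialect: header `segment_id,slice_index,inner_diameter_um,outer_diameter_um`
#' (UTF-8, comma-separated, '.' decimal). Each row is one paired inner/outer
#' diameter measurement of one vessel segment on one section image; a segment
#' present in several images contributes several rows.
#'
#' @param path CSV path
#' @return validated measurement data.frame
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_measurements(tab)
}

validate_measurements <- function(tab) {
  req <- c("segment_id", "inner_diameter_um", "outer_diameter_um")
  if (!all(req %in% names(tab))) {
    stop("measurement table needs columns ", paste(req, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(tab)
  bad <- which(!(tab$inner_diameter_um > 0))
  if (length(bad)) {
    stop("non-positive inner diameter in measurement row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(tab$outer_diameter_um < tab$inner_diameter_um)
  if (length(bad)) {
    stop("outer diameter smaller than inner diameter in measurement row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (segment ", paste(tab$segment_id[utils::head(bad, 5)], collapse = ", "), ")")
  }
  tab
}

#' Aggregate per-slice measurements into per-segment features
#'
#' All rows of a segment are averaged: mean inner diameter, mean outer
#' diameter, and wall thickness computed as half the difference of the
#' averaged outer and inner diameters (for paired rows this equals the mean
#' of the per-row wall thicknesses). Every measurement row carries equal
#' weight.
#'
#' @param table measurement data.frame (see [read_measurements()])
#' @return data.frame with one row per distinct segment ID:
#'   `segment_id`, `inner_diameter_um`, `outer_diameter_um`,
#'   `wall_thickness_um`, `n_measurements`
#' @export
aggregate_measurements <- function(table) {
  table <- validate_measurements(table)
  if (nrow(table) == 0L) {
    return(data.frame(segment_id = integer(0), inner_diameter_um = numeric(0),
                      outer_diameter_um = numeric(0),
                      wall_thickness_um = numeric(0),
                      n_measurements = integer(0)))
  }
  f <- factor(table$segment_id)
  inner <- tapply(table$inner_diameter_um, f, mean)
  outer <- tapply(table$outer_diameter_um, f, mean)
  out <- data.frame(segment_id = as.integer(levels(f)),
                    inner_diameter_um = as.numeric(inner),
                    outer_diameter_um = as.numeric(outer),
                    wall_thickness_um = 0.5 * (as.numeric(outer) - as.numeric(inner)),
                    n_measurements = as.integer(table(f)))
  out <- out[order(out$segment_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Measurement coverage of a vessel tree
#'
#' How many of the tree's segments carry at least one measurement.
#'
#' @param tree a [vessel_tree()]
#' @param features per-segment features from [aggregate_measurements()]
#' @return list with `measured`, `total`, and `percentage`
#'   (100 x measured/total, rounded to one decimal)
#' @export
coverage <- function(tree, features) {
  ids <- require_ids(tree)
  orphan <- setdiff(features$segment_id, ids)
  if (length(orphan)) {
    stop("orphan measurement: segment ID(s) ",
         paste(utils::head(orphan, 5), collapse = ", "), " not in tree")
  }
  measured <- length(unique(features$segment_id))
  total <- length(ids)
  list(measured = measured, total = total,
       percentage = round(100 * measured / total, 1))
}

#' Join per-segment features with classification labels
#'
#' Produces one row per labeled segment. Measured segments carry their
#' feature values; unmeasured segments appear with `NA` features, so that
#' groups emptied (or reduced to a single point) by missing measurements
#' remain detectable downstream.
#'
#' @param features per-segment features (one row per segment ID)
#' @param labels a `scheme_labels` object, a list of them, or a data.frame
#'   from [classify_all()]
#' @return data.frame: `segment_id`, the feature columns, one integer column
#'   per scheme, plus logical `measured`
#' @export
join_features <- function(features, labels) {
  if (anyDuplicated(features$segment_id)) {
    stop("duplicate segment ID in features: ",
         paste(unique(features$segment_id[duplicated(features$segment_id)]),
               collapse = ", "))
  }
  lab_df <- if (is.data.frame(labels)) {
    labels
  } else {
    if (inherits(labels, "scheme_labels")) labels <- list(labels)
    key <- sort(as.integer(names(labels[[1]])))
    df <- data.frame(segment_id = key)
    for (lab in labels) {
      df[[attr(lab, "scheme")]] <- as.integer(lab[as.character(key)])
    }
    df
  }
  unlabeled <- setdiff(features$segment_id, lab_df$segment_id)
  if (length(unlabeled)) {
    stop("unlabeled segment: measured segment ID(s) ",
         paste(utils::head(unlabeled, 5), collapse = ", "),
         " missing from labels")
  }
  out <- merge(lab_df, features, by = "segment_id", all.x = TRUE)
  out$measured <- out$segment_id %in% features$segment_id
  out <- out[order(out$segment_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
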