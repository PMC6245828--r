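#' Study configuration
#'
#' Single source of truth for an end-to-end validation study: where the
#' images and rating tables live, which binary grouping and tie rule to
#' use, and the measurement parameters.
#'
#' @param images Either a directory of PNG images or a named list of
#'   intensity matrices / `phantom_image`s (names become image ids).
#' @param ratings Path to a ratings CSV (`image_id`, `rater_id`, `round`,
#'   `grade`) or an equivalent data.frame.
#' @param labels Optional consensus labels: CSV path or data.frame
#'   (`image_id`, `label`). When absent, the majority vote over all rounds
#'   stands in (recorded in provenance).
#' @param out_dir Output directory for the report bundle (`NULL` = don't
#'   write).
#' @param grouping Binary grouping applied to four-grade ratings.
#' @param tie_rule Majority-vote tie rule.
#' @param config A [retinotort_config()].
#' @return A `study_config`.
#' @export
study_config <- function(images, ratings, labels = NULL, out_dir = NULL,
                         grouping = "asymptomatic_vs_symptomatic",
                         tie_rule = "higher", config = retinotort_config()) {
  structure(list(images = images, ratings = ratings, labels = labels,
                 out_dir = out_dir, grouping = grouping, tie_rule = tie_rule,
                 config = config),
            class = "study_config")
}

load_study_images <- function(images) {
  if (is.character(images)) {
    files <- sort(list.files(images, pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) stop_invalid(paste("no PNG images found in", images))
    out <- lapply(files, read_fundus)
    names(out) <- sub("\\.png$", "", basename(files), ignore.case = TRUE)
    return(out)
  }
  out <- lapply(images, function(im) {
    if (inherits(im, "phantom_image")) im$raster else as_intensity(im)
  })
  if (is.null(names(out))) names(out) <- sprintf("img%03d", seq_along(out))
  out
}

load_ratings <- function(ratings) {
  df <- if (is.character(ratings)) utils::read.csv(ratings, stringsAsFactors = FALSE) else ratings
  as_panel(df)
}

load_labels <- function(labels) {
  df <- if (is.character(labels)) utils::read.csv(labels, stringsAsFactors = FALSE) else labels
  if ("class" %in% names(df) && !"label" %in% names(df)) df$label <- df$class
  if (!all(c("image_id", "label") %in% names(df))) {
    stop_invalid("labels need columns image_id and label (or class)")
  }
  df[c("image_id", "label")]
}

#' Run an end-to-end validation study
#'
#' Measures every image (four tortuosity metrics, integrated per retina),
#' analyzes the rating panel (kappa matrix, majority votes, consensus
#' percentages), and validates each metric against the binary consensus
#' labels (ROC curve + AUC), together with the single ROC point of every
#' (rater, round) prediction. The report regenerates bit-identically from
#' the same inputs.
#'
#' @param config A [study_config()].
#' @return A `study_report`: list with `scores` (image x metric data.frame),
#'   `per_image` (list of `tree_tortuosity`), `kappa`, `votes`, `consensus`
#'   (per round), `roc` (per metric), `expert_points` (per rater-round),
#'   `labels`, `provenance`. Written as `report.json` plus CSV tables when
#'   `out_dir` is set.
#' @export
run_study <- function(config) {
  if (!inherits(config, "study_config")) stop_invalid("expected a study_config")
  imgs <- load_study_images(config$images)
  panel <- load_ratings(config$ratings)

  offenders <- setdiff(unique(panel$image_id), names(imgs))
  if (length(offenders) > 0L) {
    stop_invalid(paste("rated images missing from the image set:",
                       paste(sort(offenders), collapse = ", ")))
  }

  reports <- lapply(imgs, measure_image, config = config$config)
  metrics <- c("hart", "grisan", "trucco", "onkaew")
  scores <- data.frame(image_id = names(reports), stringsAsFactors = FALSE)
  for (m in metrics) {
    scores[[m]] <- vapply(reports, function(r) r$totals[[m]], numeric(1))
  }
  rownames(scores) <- NULL

  # binary view of the ratings
  grouping <- grade_grouping(config$grouping)
  bin_panel <- panel
  if (any(panel$grade > 1L)) {
    bin_panel$grade <- as.integer(panel$grade %in% grouping$class1)
  }

  labels_flagged <- is.null(config$labels)
  labels <- if (labels_flagged) {
    mv <- majority_vote(bin_panel, tie_rule = config$tie_rule)
    data.frame(image_id = mv$image_id, label = mv$label, stringsAsFactors = FALSE)
  } else {
    load_labels(config$labels)
  }
  rated <- sort(unique(bin_panel$image_id))
  labels <- labels[labels$image_id %in% rated, , drop = FALSE]

  kappa <- kappa_matrix(bin_panel, reference = labels, tie_rule = config$tie_rule)
  votes <- lapply(stats::setNames(sort(unique(bin_panel$round)),
                                  sort(unique(bin_panel$round))),
                  function(rd) majority_vote(bin_panel, rounds = rd,
                                             tie_rule = config$tie_rule))
  consensus <- lapply(stats::setNames(sort(unique(bin_panel$round)),
                                      sort(unique(bin_panel$round))),
                      function(rd) {
    sub <- bin_panel[bin_panel$round == rd, ]
    consensus_summary(rating_table(sub$image_id, sub$rater_id, sub$grade,
                                   round = rd, scale = 0:1))
  })

  ref <- stats::setNames(labels$label, labels$image_id)
  rocs <- lapply(stats::setNames(metrics, metrics), function(m) {
    sc <- stats::setNames(scores[[m]], scores$image_id)
    roc_curve(sc[names(ref)], ref)
  })
  expert_points <- list()
  for (rd in sort(unique(bin_panel$round))) {
    sub <- bin_panel[bin_panel$round == rd, ]
    for (ra in sort(unique(sub$rater_id))) {
      v <- sub[sub$rater_id == ra, ]
      pred <- stats::setNames(v$grade, v$image_id)
      expert_points[[paste0(ra, "_", rd)]] <- expert_roc_point(pred[names(ref)], ref)
    }
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("retinotort")),
    grouping = grouping$name,
    tie_rule = config$tie_rule,
    labels_source = if (labels_flagged) "majority_vote" else "explicit",
    n_images = length(imgs),
    measurement = config$config[setdiff(names(config$config), "threshold")])

  report <- structure(list(scores = scores, per_image = reports, kappa = kappa,
                           votes = votes, consensus = consensus, roc = rocs,
                           expert_points = expert_points, labels = labels,
                           provenance = provenance),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report: %d images, %d expert ROC points, %d metric curves>\n",
              nrow(x$scores), length(x$expert_points), length(x$roc)))
  aucs <- vapply(x$roc, `[[`, numeric(1), "auc")
  cat("AUC:", paste(sprintf("%s=%.3f", names(aucs), aucs), collapse = "  "), "\n")
  invisible(x)
}

#' Write a study report bundle
#'
#' `report.json` (numbers at 6 significant digits) plus per-table CSVs:
#' `tortuosity.csv`, `kappa.csv`, `labels.csv` and one `roc_<metric>.csv`
#' per metric.
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if needed).
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(round6(report$scores), file.path(out_dir, "tortuosity.csv"),
                   row.names = FALSE)
  km <- as.data.frame(round6(unclass(report$kappa)))
  km <- cbind(pair = rownames(km), km)
  utils::write.csv(km, file.path(out_dir, "kappa.csv"), row.names = FALSE)
  utils::write.csv(report$labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  for (m in names(report$roc)) {
    rc <- report$roc[[m]]
    utils::write.csv(round6(data.frame(threshold = rc$thresholds, fpr = rc$fpr,
                                       tpr = rc$tpr)),
                     file.path(out_dir, paste0("roc_", m, ".csv")),
                     row.names = FALSE)
  }
  json <- list(
    provenance = report$provenance,
    auc = lapply(report$roc, function(r) signif(r$auc, 6)),
    consensus = lapply(report$consensus, function(v) as.list(signif(v, 6))),
    expert_points = lapply(report$expert_points, function(p) {
      list(sensitivity = signif(p$sensitivity, 6), specificity = signif(p$specificity, 6))
    }),
    totals = stats::setNames(
      lapply(seq_len(nrow(report$scores)), function(i) {
        as.list(signif(unlist(report$scores[i, -1L]), 6))
      }), report$scores$image_id))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

round6 <- function(df) {
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  df
}
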