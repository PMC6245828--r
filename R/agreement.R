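#' The four-grade tortuosity scale
#'
#' Ordinal grades used for manual tortuosity rating: 0 none, 1 mild,
#' 2 moderate, 3 severe.
#'
#' @return Named integer vector mapping labels to grade codes.
#' @export
grade_scale <- function() {
  c(none = 0L, mild = 1L, moderate = 2L, severe = 3L)
}

#' Binary groupings of the four-grade scale
#'
#' Two clinically meaningful groupings of the grades:
#' `"tortuous_vs_non"` separates no visible tortuosity from any tortuosity
#' (0 vs 1-3); `"asymptomatic_vs_symptomatic"` groups none and mild (which
#' carries no clinical risk) against moderate and severe (which can require
#' treatment), i.e. 0-1 vs 2-3.
#'
#' @param name Which grouping.
#' @return A `binary_grouping`: list with `name`, `class0`, `class1`.
#' @export
grade_grouping <- function(name = c("asymptomatic_vs_symptomatic", "tortuous_vs_non")) {
  name <- match.arg(name)
  g <- switch(name,
    asymptomatic_vs_symptomatic = list(class0 = 0:1, class1 = 2:3),
    tortuous_vs_non = list(class0 = 0L, class1 = 1:3))
  structure(c(list(name = name), g), class = "binary_grouping")
}

#' Build a rating table
#'
#' Long-format table of ordinal grades: one row per (image, rater) cell of
#' one rating round.
#'
#' @param image_id,rater_id,grade Equal-length vectors.
#' @param round Round label (e.g. "R1", "R2", "Rc").
#' @param scale Vector of valid grade codes; defaults to the four-grade
#'   scale. Use `0:1` for binary tables.
#' @return A data.frame of class `rating_table` with attributes `round` and
#'   `scale`.
#' @export
rating_table <- function(image_id, rater_id, grade, round = "R1",
                         scale = grade_scale()) {
  grade <- as.integer(grade)
  if (!all(grade %in% scale)) stop_invalid("grades outside the declared scale")
  df <- data.frame(image_id = as.character(image_id),
                   rater_id = as.character(rater_id),
                   grade = grade, stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("image_id", "rater_id")])) {
    stop_invalid("duplicate (image, rater) cells in rating table")
  }
  structure(df, round = round, scale = unname(as.integer(scale)),
            class = c("rating_table", "data.frame"))
}

#' Collapse a four-grade rating table to a binary one
#'
#' Maps every cell through a [grade_grouping()]; per-rater class counts
#' equal the sums of the grouped grade counts.
#'
#' @param table A `rating_table` on the four-grade scale.
#' @param grouping A `binary_grouping`.
#' @return A binary `rating_table` (grades 0/1).
#' @export
group_grades <- function(table, grouping = grade_grouping()) {
  if (!inherits(grouping, "binary_grouping")) stop_invalid("expected a binary_grouping")
  if (!all(table$grade %in% c(grouping$class0, grouping$class1))) {
    stop_invalid("table contains grades outside the grouping")
  }
  rating_table(table$image_id, table$rater_id,
               as.integer(table$grade %in% grouping$class1),
               round = attr(table, "round"), scale = 0:1)
}

#' Collapse marginal grade counts through a binary grouping
#'
#' Operates on a counts matrix (grades x raters), such as the bundled
#' first-round marginals, returning the 2 x raters class counts.
#'
#' @param counts Numeric matrix with one row per grade code (rownames are
#'   grade codes) and one column per rater.
#' @inheritParams group_grades
#' @return A 2 x raters matrix with rows `class0`, `class1`.
#' @export
group_grade_counts <- function(counts, grouping = grade_grouping()) {
  counts <- as.matrix(counts)
  g <- as.integer(rownames(counts))
  if (any(is.na(g))) stop_invalid("counts rownames must be grade codes")
  out <- rbind(class0 = colSums(counts[g %in% grouping$class0, , drop = FALSE]),
               class1 = colSums(counts[g %in% grouping$class1, , drop = FALSE]))
  out
}

#' Bundled five-expert rating marginals
#'
#' Marginal grade counts from a five-expert grading study of 60 fundus
#' images of diabetic patients (two individual rounds plus majority-vote
#' and consensus summaries). These are marginal counts only — the per-image
#' labels behind them were never published — so they support consistency
#' checks, not per-image agreement statistics.
#'
#' @param which One of `"r1_four_grade"` (round-1 counts on the four-grade
#'   scale, grades x experts), `"binary"` (asymptomatic/symptomatic counts
#'   for rounds R1 and R2, long format), `"votes"` (binary counts of the
#'   majority-vote and consensus summaries V_R1, V_R2, V_R1R2, R_c).
#' @return A data.frame (or matrix for `"r1_four_grade"`).
#' @export
rating_marginals <- function(which = c("r1_four_grade", "binary", "votes")) {
  which <- match.arg(which)
  file <- switch(which,
    r1_four_grade = "expert_counts_r1_four_grade.csv",
    binary = "expert_counts_binary.csv",
    votes = "vote_counts_binary.csv")
  path <- system.file("extdata", file, package = "retinotort", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (which == "r1_four_grade") {
    m <- as.matrix(df[, -1L])
    rownames(m) <- df$grade
    return(m)
  }
  df
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two raters:
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)}, with observed agreement `p_o`
#' and chance agreement `p_e` from the product of the marginal label
#' distributions.
#'
#' @param a,b Equal-length rating vectors on the same scale.
#' @return Kappa in [-1, 1]. When both raters use a single identical label
#'   (`p_e = 1`), agreement beyond chance is undefined: returns `NA` with
#'   attribute `undefined = TRUE`.
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("rating vectors must have equal length")
  if (length(a) < 2L) stop_invalid("need at least 2 rated items")
  lev <- sort(unique(c(a, b)))
  fa <- factor(a, levels = lev)
  fb <- factor(b, levels = lev)
  n <- length(a)
  po <- sum(fa == fb) / n
  pe <- sum((table(fa) / n) * (table(fb) / n))
  if (abs(1 - pe) < .Machine$double.eps * 8) {
    return(structure(NA_real_, undefined = TRUE))
  }
  (po - pe) / (1 - pe)
}

#' Interpret a kappa value on the standard agreement bands
#'
#' Bands: [0, 0.20] slight, (0.20, 0.40] fair, (0.40, 0.60] moderate,
#' (0.60, 0.80] substantial, (0.80, 1] almost perfect; negative values are
#' labelled "less than chance".
#'
#' @param value Kappa value(s) in [-1, 1].
#' @return Character vector of band labels.
#' @export
interpret_kappa <- function(value) {
  if (any(!is.na(value) & (value < -1 | value > 1))) {
    stop_invalid("kappa must lie in [-1, 1]")
  }
  vapply(value, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v < 0) "less than chance"
    else if (v <= 0.20) "slight"
    else if (v <= 0.40) "fair"
    else if (v <= 0.60) "moderate"
    else if (v <= 0.80) "substantial"
    else "almost perfect"
  }, character(1))
}

# internal: panel = long data.frame image_id, rater_id, round, grade
as_panel <- function(x) {
  if (inherits(x, "rating_table")) {
    x <- data.frame(image_id = x$image_id, rater_id = x$rater_id,
                    round = attr(x, "round"), grade = x$grade,
                    stringsAsFactors = FALSE)
  } else if (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, logical(1), "rating_table"))) {
    x <- do.call(rbind, lapply(x, as_panel))
  }
  req <- c("image_id", "rater_id", "round", "grade")
  if (!all(req %in% names(x))) {
    stop_invalid(paste("panel needs columns:", paste(req, collapse = ", ")))
  }
  x
}

#' Majority-vote labels over rating rounds
#'
#' For each image, the most voted grade over all votes cast in the selected
#' rounds (each expert-round pair contributes one vote, so pooling two
#' rounds gives two votes per expert). Exact ties are resolved by
#' `tie_rule` and flagged.
#'
#' @param panel A `rating_table`, list of them, or long data.frame with
#'   columns `image_id`, `rater_id`, `round`, `grade`.
#' @param rounds Round labels to pool; `NULL` pools all.
#' @param tie_rule `"higher"` (default, the clinically conservative choice:
#'   the more severe grade wins) or `"lower"`.
#' @return data.frame `image_id`, `label`, `tie`, with attribute `source`.
#' @export
majority_vote <- function(panel, rounds = NULL, tie_rule = c("higher", "lower")) {
  tie_rule <- match.arg(tie_rule)
  panel <- as_panel(panel)
  if (!is.null(rounds)) panel <- panel[panel$round %in% rounds, , drop = FALSE]
  if (nrow(panel) == 0L) stop_invalid("no votes in the selected rounds")
  res <- lapply(split(panel$grade, panel$image_id), function(g) {
    tab <- table(g)
    top <- as.integer(names(tab)[tab == max(tab)])
    tie <- length(top) > 1L
    label <- if (tie_rule == "higher") max(top) else min(top)
    c(label = label, tie = as.integer(tie))
  })
  out <- data.frame(image_id = names(res),
                    label = vapply(res, `[[`, numeric(1), "label"),
                    tie = vapply(res, `[[`, numeric(1), "tie") == 1,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "source") <- if (is.null(rounds)) "all" else paste(rounds, collapse = "+")
  out
}

#' Pairwise Cohen-kappa matrix for a rating panel
#'
#' Computes kappa between every (rater, round) pair, including cross-round
#' pairs (whose diagonal blocks give the intra-rater agreement), and
#' optionally against the majority-vote vectors of each round and their
#' union, and against an external reference (consensus) labelling.
#'
#' @inheritParams majority_vote
#' @param include_votes Add V_<round> columns (majority vote per round) and
#'   V_<all rounds> (pooled vote).
#' @param reference Optional data.frame `image_id`, `label` of consensus
#'   labels, added as column/row `Rc`.
#' @return A `kappa_matrix`: symmetric numeric matrix with `NA` (attribute
#'   carried per-cell is lost; undefined cells are `NA`) and dimnames
#'   `<rater>_<round>`.
#' @export
kappa_matrix <- function(panel, include_votes = TRUE, reference = NULL,
                         tie_rule = "higher") {
  panel <- as_panel(panel)
  images <- sort(unique(panel$image_id))
  vecs <- list()
  for (rd in sort(unique(panel$round))) {
    sub <- panel[panel$round == rd, ]
    for (ra in sort(unique(sub$rater_id))) {
      v <- sub[sub$rater_id == ra, ]
      if (!setequal(v$image_id, images)) {
        stop_invalid(sprintf("rater %s round %s does not cover the shared image set", ra, rd))
      }
      vecs[[paste0(ra, "_", rd)]] <- v$grade[match(images, v$image_id)]
    }
  }
  if (include_votes) {
    rds <- sort(unique(panel$round))
    for (rd in rds) {
      mv <- majority_vote(panel, rounds = rd, tie_rule = tie_rule)
      vecs[[paste0("V_", rd)]] <- mv$label[match(images, mv$image_id)]
    }
    if (length(rds) > 1L) {
      mv <- majority_vote(panel, rounds = rds, tie_rule = tie_rule)
      vecs[[paste0("V_", paste(rds, collapse = ""))]] <-
        mv$label[match(images, mv$image_id)]
    }
  }
  if (!is.null(reference)) {
    if (!setequal(reference$image_id, images)) {
      stop_invalid("reference labels do not cover the shared image set")
    }
    vecs[["Rc"]] <- reference$label[match(images, reference$image_id)]
  }
  nm <- names(vecs)
  k <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (j < i) { k[i, j] <- k[j, i]; next }
      val <- cohen_kappa(vecs[[i]], vecs[[j]])
      k[i, j] <- as.numeric(val)
    }
  }
  structure(k, class = c("kappa_matrix", "matrix"))
}

#' Expert consensus percentages
#'
#' For a single-round table with R raters, the percentage of images where
#' all R raters agree on the modal label, where at least R-1 agree, and
#' where at least R-2 agree. Monotone non-decreasing as the requirement is
#' relaxed.
#'
#' @param table A `rating_table` (one round).
#' @param exactly Use "exactly R-1 coincidences" instead of "at least" for
#'   the middle figure.
#' @return Named numeric vector of percentages: `full`, `all_but_one`,
#'   `all_but_two`.
#' @export
consensus_summary <- function(table, exactly = FALSE) {
  panel <- as_panel(table)
  counts <- tapply(panel$grade, panel$image_id, function(g) max(table(g)))
  r <- length(unique(panel$rater_id))
  if (r < 3L) stop_invalid("consensus summary needs at least 3 raters")
  n <- length(counts)
  full <- 100 * sum(counts >= r) / n
  mid <- if (exactly) 100 * sum(counts == r - 1L) / n else 100 * sum(counts >= r - 1L) / n
  low <- 100 * sum(counts >= r - 2L) / n
  c(full = full, all_but_one = mid, all_but_two = low)
}

#' Closed-form expected kappa for two confusion-matrix raters
#'
#' For two raters whose reports follow row-stochastic confusion matrices
#' given the true grade, and a prior over true grades, the population
#' Cohen kappa is computable in closed form from the joint report
#' distribution. Used as an analytic oracle for panel simulations.
#'
#' @param prior Probability vector over true grades.
#' @param conf_a,conf_b Row-stochastic confusion matrices (true x reported).
#' @return Expected kappa.
#' @export
expected_kappa <- function(prior, conf_a, conf_b) {
  conf_a <- as.matrix(conf_a); conf_b <- as.matrix(conf_b)
  joint <- t(conf_a) %*% (prior * conf_b)   # reported_a x reported_b
  po <- sum(diag(joint))
  pe <- sum(rowSums(joint) * colSums(joint))
  (po - pe) / (1 - pe)
}
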