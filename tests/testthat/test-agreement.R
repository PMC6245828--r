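test_that("bundled marginals are conserved and collapse exactly to the binary counts", {
  four <- rating_marginals("r1_four_grade")
  expect_equal(unname(colSums(four)), rep(60, 5))
  bin <- rating_marginals("binary")
  r1 <- bin[bin$round == "R1", ]
  grouped <- group_grade_counts(four, grade_grouping("asymptomatic_vs_symptomatic"))
  for (e in paste0("E", 1:5)) {
    expect_equal(unname(grouped["class0", e]), r1[r1$class == 0, e][[1]])
    expect_equal(unname(grouped["class1", e]), r1[r1$class == 1, e][[1]])
  }
  # tortuous / non-tortuous grouping: class0 is the none row alone
  tort <- group_grade_counts(four, grade_grouping("tortuous_vs_non"))
  expect_equal(unname(tort["class0", ]), unname(four["0", ]))
  expect_equal(unname(tort["class1", ]), unname(colSums(four[c("1", "2", "3"), ])))
  # vote marginals also sum to the dataset size
  votes <- rating_marginals("votes")
  expect_equal(as.numeric(tapply(votes$count, votes$source, sum)), rep(60, 4))
})

test_that("per-cell grade grouping preserves per-rater class counts", {
  set.seed(7)
  tab <- rating_table(rep(sprintf("i%02d", 1:20), each = 4),
                      rep(paste0("E", 1:4), 20),
                      sample(0:3, 80, replace = TRUE), round = "R1")
  for (gname in c("asymptomatic_vs_symptomatic", "tortuous_vs_non")) {
    g <- grade_grouping(gname)
    b <- group_grades(tab, g)
    for (e in paste0("E", 1:4)) {
      expect_equal(sum(b$grade[b$rater_id == e] == 1),
                   sum(tab$grade[tab$rater_id == e] %in% g$class1))
    }
  }
  expect_true(all(group_grades(rating_table("i1", c("a", "b"), c(0, 0)),
                               grade_grouping())$grade == 0))
})

test_that("Cohen kappa matches hand-worked cases and flags the degenerate marginal", {
  expect_equal(cohen_kappa(c(0, 1, 2, 0, 1), c(0, 1, 2, 0, 1)), 1)
  expect_equal(cohen_kappa(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(cohen_kappa(c(0, 1), c(1, 0)), -1)
  und <- cohen_kappa(rep(2, 5), rep(2, 5))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  expect_error(cohen_kappa(1:3, 1:4), class = "retinotort_invalid_input")
})

test_that("kappa equals the confusion-matrix computation on random panels", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    a <- sample(0:3, n, replace = TRUE)
    b <- sample(0:3, n, replace = TRUE)
    k <- cohen_kappa(a, b)
    if (is.na(k)) next
    expect_equal(as.numeric(k), kappa_from_confusion(a, b), tolerance = 1e-12)
  }
})

test_that("kappa agrees with the e1071 implementation and is symmetric", {
  skip_if_not_installed("e1071")
  set.seed(5)
  for (i in 1:20) {
    a <- sample(0:1, 60, replace = TRUE)
    b <- sample(0:1, 60, replace = TRUE)
    cm <- table(factor(a, 0:1), factor(b, 0:1))
    expect_equal(as.numeric(cohen_kappa(a, b)),
                 e1071::classAgreement(cm)$kappa, tolerance = 1e-10)
    expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
  }
})

test_that("kappa matrix covers rater, vote and reference vectors symmetrically", {
  set.seed(11)
  ids <- sprintf("i%02d", 1:30)
  g1 <- sample(0:1, 30, replace = TRUE)
  panel <- rbind(
    data.frame(image_id = ids, rater_id = "A", round = "R1", grade = g1),
    data.frame(image_id = ids, rater_id = "B", round = "R1", grade = g1),
    data.frame(image_id = ids, rater_id = "A", round = "R2",
               grade = sample(0:1, 30, replace = TRUE)),
    data.frame(image_id = ids, rater_id = "B", round = "R2",
               grade = sample(0:1, 30, replace = TRUE)))
  ref <- data.frame(image_id = ids, label = g1)
  km <- kappa_matrix(panel, reference = ref)
  expect_true(all(c("A_R1", "B_R1", "A_R2", "B_R2", "V_R1", "V_R2", "V_R1R2", "Rc")
                  %in% rownames(km)))
  expect_equal(km["A_R1", "B_R1"], 1)           # identical raters
  expect_equal(km["A_R1", "Rc"], 1)             # reference built from A_R1
  expect_equal(unclass(km), t(unclass(km)))     # symmetry
  # permuting image order changes nothing
  perm <- panel[sample(nrow(panel)), ]
  expect_equal(unclass(kappa_matrix(perm, reference = ref)), unclass(km))
})

test_that("majority vote pools rounds and resolves ties conservatively", {
  ids <- c("a", "a", "a", "a", "a")
  p <- data.frame(image_id = ids, rater_id = paste0("E", 1:5), round = "R1",
                  grade = c(0, 0, 0, 1, 1))
  mv <- majority_vote(p)
  expect_equal(mv$label, 0)
  expect_false(mv$tie)
  # pooled 5 + 5 votes splitting evenly: higher grade wins, tie flagged
  p2 <- rbind(p, data.frame(image_id = ids, rater_id = paste0("E", 1:5),
                            round = "R2", grade = c(1, 1, 1, 0, 0)))
  mv2 <- majority_vote(p2, rounds = c("R1", "R2"))
  expect_equal(mv2$label, 1)
  expect_true(mv2$tie)
  expect_equal(majority_vote(p2, rounds = c("R1", "R2"), tie_rule = "lower")$label, 0)
  # unanimity
  p3 <- data.frame(image_id = ids, rater_id = paste0("E", 1:5), round = "R1", grade = 2)
  expect_equal(majority_vote(p3)$label, 2)
})

test_that("consensus percentages match enumeration and are monotone", {
  ids <- rep(sprintf("i%d", 1:4), each = 5)
  grades <- c(1, 1, 1, 1, 1,   0, 0, 0, 0, 1,   1, 1, 1, 0, 0,   1, 1, 0, 0, 2)
  tab <- rating_table(ids, rep(paste0("E", 1:5), 4), grades, round = "R1")
  cs <- consensus_summary(tab)
  expect_equal(unname(cs), c(25, 50, 75))
  expect_equal(unname(consensus_summary(tab, exactly = TRUE)[["all_but_one"]]), 25)
  # unanimity everywhere
  uni <- rating_table(ids, rep(paste0("E", 1:5), 4), rep(1, 20), round = "R1")
  expect_equal(unname(consensus_summary(uni)), c(100, 100, 100))
  # monotone on random panels
  set.seed(21)
  for (i in 1:20) {
    tabr <- rating_table(rep(sprintf("i%02d", 1:12), each = 5),
                         rep(paste0("E", 1:5), 12),
                         sample(0:3, 60, replace = TRUE), round = "R1")
    v <- consensus_summary(tabr)
    expect_true(v[["full"]] <= v[["all_but_one"]])
    expect_true(v[["all_but_one"]] <= v[["all_but_two"]])
  }
})

test_that("kappa interpretation follows the standard bands", {
  expect_equal(interpret_kappa(0.15), "slight")
  expect_equal(interpret_kappa(0.35), "fair")
  expect_equal(interpret_kappa(0.5), "moderate")
  expect_equal(interpret_kappa(0.61), "substantial")
  expect_equal(interpret_kappa(0.83), "almost perfect")
  expect_equal(interpret_kappa(-0.2), "less than chance")
  expect_equal(interpret_kappa(c(0.20, 0.40, 0.60, 0.80, 1)),
               c("slight", "fair", "moderate", "substantial", "almost perfect"))
  expect_error(interpret_kappa(1.2), class = "retinotort_invalid_input")
})
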