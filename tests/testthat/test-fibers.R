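make_label_square <- function(H = 60L, W = 60L, r0 = 5L, size = 50L) {
  lab <- matrix(0L, H, W)
  lab[r0:(r0 + size - 1L), r0:(r0 + size - 1L)] <- 1L
  structure(list(labels = lab, n_fibers = 1L, boundary_threshold = 0,
                 params = segmentation_params()), class = "label_map")
}

test_that("fiber CSA is the label pixel count at 1 um^2 per pixel", {
  panel <- small_panel()
  fibers <- make_label_square()
  st <- channel_stack(array(0L, dim = c(60L, 60L, 3L)), panel)
  ts <- threshold_set(rep("*", 3L), panel$marker_name, rep(5, 3L))
  tab <- build_fiber_table(fibers, st, ts)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$csa_um2, 2500)
  expect_identical(tab$frac_MarkerA, 0)

  # fiber fully inside a positive region scores fraction 1
  px <- array(0L, dim = c(60L, 60L, 3L)); px[, , 1L] <- 9L
  tab2 <- build_fiber_table(fibers, channel_stack(px, panel), ts)
  expect_identical(tab2$frac_MarkerA, 1)
  expect_true(tab2$pos_MarkerA)
})

test_that("fiber marker fractions match per-label pixel counting", {
  panel <- small_panel()
  set.seed(91)
  for (rep in 1:5) {
    lab <- matrix(0L, 40L, 40L)
    lab[3:18, 3:18] <- 1L; lab[22:37, 3:18] <- 2L; lab[3:18, 22:37] <- 3L
    fibers <- structure(list(labels = lab, n_fibers = 3L,
                             boundary_threshold = 0,
                             params = segmentation_params()),
                        class = "label_map")
    st <- random_stack(panel, 40L, 40L)
    ts <- threshold_set(rep("*", 3L), panel$marker_name, c(12, 30, 44))
    tab <- build_fiber_table(fibers, st, ts)
    for (i in 1:3) {
      want <- oracle_fiber_fractions(lab, st$pixels[, , i],
                                     ts$threshold[i])
      col <- paste0("frac_", gsub("[^A-Za-z0-9]+", "_",
                                  panel$marker_name[i]))
      expect_equal(unname(tab[[col]]), unname(want))
    }
  }
})

test_that("empty label maps give an empty, well-formed table", {
  panel <- small_panel()
  empty <- structure(list(labels = matrix(0L, 10L, 10L), n_fibers = 0L,
                          boundary_threshold = 0,
                          params = segmentation_params()),
                     class = "label_map")
  st <- channel_stack(array(0L, dim = c(10L, 10L, 3L)), panel)
  ts <- threshold_set(rep("*", 3L), panel$marker_name, rep(1, 3L))
  tab <- build_fiber_table(empty, st, ts)
  expect_identical(nrow(tab), 0L)
  expect_true(all(c("csa_um2", "frac_MarkerA", "pos_MarkerA") %in%
                    names(tab)))
})

test_that("positivity rules are inclusive at-the-threshold area fractions", {
  expect_true(score_positivity(0.10, "MYH3"))      # exactly 10% -> positive
  expect_false(score_positivity(0.0999, "MYH3"))
  expect_true(score_positivity(0.06, "CTGF"))      # CTGF rule is 5%
  expect_false(score_positivity(0.04, "CTGF"))
  expect_true(score_positivity(0.05, "CTGF"))
  custom <- positivity_rules(default = 0.2, overrides = c(MarkerA = 0.5))
  expect_false(score_positivity(0.3, "MarkerA", custom))
  expect_true(score_positivity(0.3, "MarkerB", custom))
  expect_error(positivity_rules(default = 0), "default > 0")
})

test_that("fiber class percentages count flag combinations", {
  flags <- function(myh3, cd56, ctgf = FALSE, pdgfa = FALSE, tgfb = FALSE) {
    data.frame(pos_MYH3 = myh3, pos_CD56 = cd56, pos_CTGF = ctgf,
               pos_PDGFA = pdgfa, pos_TGFb = tgfb)
  }
  tab <- cbind(data.frame(fiber_id = 1:10, csa_um2 = 100),
               flags(rep(c(TRUE, FALSE), c(3L, 7L)), FALSE))
  pc <- class_percentages(tab)
  expect_identical(unname(pc["MYH3"]), 30)

  none <- cbind(data.frame(fiber_id = 1:4, csa_um2 = 100),
                flags(FALSE, FALSE))
  expect_true(all(class_percentages(none) == 0))

  # 2 MYH3+CD56+, 1 MYH3-CD56+, 1 double-negative
  mixed <- cbind(data.frame(fiber_id = 1:4, csa_um2 = 100),
                 flags(c(TRUE, TRUE, FALSE, FALSE),
                       c(TRUE, TRUE, TRUE, FALSE)))
  pm <- class_percentages(mixed)
  expect_identical(unname(pm["CD56"]), 75)
  expect_identical(unname(pm["MYH3-CD56+"]), 25)

  # invariant under row permutation
  perm <- mixed[sample(4L), ]
  expect_identical(class_percentages(perm), pm)

  expect_error(class_percentages(mixed[0L, ]), "empty")
})

test_that("CSA summaries report mean, sample SD, histogram and ECDF", {
  tab <- data.frame(fiber_id = 1:3, group = "control", csa_um2 = c(1, 2, 3))
  s <- suppressWarnings(csa_summary(tab, bin_width = 1))
  expect_identical(s$stats$mean_csa, 2)
  expect_identical(s$stats$sd_csa, 1)      # sample (n-1) SD
  expect_identical(max(s$ecdf$ecdf), 1)
  expect_equal(sum(s$histogram$rel_freq[s$histogram$group == "control"]), 1)

  two <- rbind(tab,
               data.frame(fiber_id = 4:9, group = "mild",
                          csa_um2 = c(10, 20, 30, 40, 50, 60)))
  expect_warning(csa_summary(two, bin_width = 25), "skipped")
  s2 <- suppressWarnings(csa_summary(two, bin_width = 25))
  for (g in c("control", "mild")) {
    expect_equal(sum(s2$histogram$rel_freq[s2$histogram$group == g]), 1)
    e <- s2$ecdf[s2$ecdf$group == g, ]
    expect_identical(e$ecdf[nrow(e)], 1)
    expect_true(all(diff(e$ecdf) >= 0))
  }
})
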