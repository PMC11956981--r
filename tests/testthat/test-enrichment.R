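test_that("mask merging takes the per-pixel maximum label", {
  a <- matrix(0L, 4, 4)
  b <- matrix(sample(0:2, 16, TRUE), 4, 4)
  expect_equal(merge_masks(a, b), b)          # zero mask is the identity
  a2 <- matrix(1L, 4, 4); b2 <- matrix(2L, 4, 4)
  expect_true(all(merge_masks(a2, b2) == 2L)) # tumor label wins
  expect_equal(merge_masks(a2, b), merge_masks(b, a2))
  expect_error(merge_masks(a, matrix(0L, 3, 3)), "shapes")
})

test_that("ghost nuclei present in only one endpoint are removed", {
  base <- matrix(0L, 10, 10)
  a <- base; a[2:4, 2:4] <- 2L; a[7:9, 7:9] <- 1L
  b <- base; b[2:4, 2:4] <- 2L                 # the grade-1 nucleus is a ghost
  merged <- merge_masks(a, b)
  clean <- remove_ghost_nuclei(merged, a, b)
  expect_true(all(clean[2:4, 2:4] == 2L))      # shared nucleus kept
  expect_true(all(clean[7:9, 7:9] == 0L))      # ghost removed
  expect_equal(remove_ghost_nuclei(base, base, base), base)
})

test_that("composite building reassigns conflicts with a fair seeded coin", {
  nuc <- matrix(0L, 20, 20); nuc[1:10, ] <- 2L; nuc[11:15, ] <- 1L
  vasc <- matrix(0L, 20, 20)
  comp <- build_composite(nuc, vasc, seed = 1)
  expect_equal(comp, build_composite(nuc, vasc, seed = 999))  # no randomness used
  expect_setequal(unique(as.integer(comp)), c(0L, 2L, 3L))
  # 100-pixel conflict region: about half goes each way
  vasc2 <- matrix(0L, 20, 20); vasc2[1:5, 1:20] <- 1L
  comp2 <- build_composite(nuc, vasc2, seed = 7)
  n_vasc <- sum(comp2[1:5, ] == 1L)
  expect_lt(abs(n_vasc - 50), 3 * sqrt(100 * 0.25))
  expect_identical(build_composite(nuc, vasc2, seed = 7),
                   build_composite(nuc, vasc2, seed = 7))
})

test_that("component Jaccard indexes match hand counts", {
  comp <- matrix(0L, 10, 10)
  comp[1:2, 1:5] <- 3L                        # tumor = 10 px
  b_exact <- matrix(0L, 10, 10); b_exact[1:2, 1:5] <- 1L
  expect_equal(unname(jaccard_components(b_exact, comp)["J_3"]), 1)
  # B a 10-pixel region overlapping M_1 (10 px) in 5 pixels -> 5/15
  comp2 <- matrix(0L, 10, 10); comp2[5, 1:10] <- 1L
  b2 <- matrix(0L, 10, 10); b2[5, 6:10] <- 1L; b2[6, 6:10] <- 1L
  expect_equal(unname(jaccard_components(b2, comp2)["J_1"]), 5 / 15)
  # empty B against nonempty component -> 0; empty union -> missing
  b0 <- matrix(0L, 10, 10)
  expect_equal(unname(jaccard_components(b0, comp2)["J_1"]), 0)
  expect_true(is.na(jaccard_components(b0, comp2)["J_3"]))
  # symmetry of the Jaccard index itself
  m1 <- comp2 == 1L
  expect_equal(sum(b2 & m1) / sum(b2 | m1), sum(m1 & b2) / sum(m1 | b2))
})

make_enr_cohort <- function(n, seed = 1) {
  # synthetic binary/composite pairs: each patch's delta overlaps its own
  # tumor region strongly; boxes are large enough that any two overlap, so
  # baseline Jaccards stay positive and ratios continuous
  with_seed2(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      comp <- matrix(0L, 20, 20)
      r0 <- sample(1:8, 1); c0 <- sample(1:8, 1)
      comp[r0:(r0 + 11), c0:(c0 + 11)] <- 3L
      bin <- matrix(0L, 20, 20)
      bin[r0:(r0 + 11), c0:(c0 + 11)] <-
        matrix(as.integer(runif(144) < 0.8), 12, 12)
      tibble::tibble(patch_id = sprintf("p%03d", i), transition = "1_to_2",
                     binary = list(bin), composite = list(comp))
    })
  })
}

test_that("enrichment recovers self-alignment against random baselines", {
  cohort <- make_enr_cohort(30)
  tab <- enrichment_analysis(cohort, seed = 3)
  agg <- enrichment_summary(tab)
  tum <- agg[agg$code == 3, ]
  expect_gt(tum$median_ratio, 1)
  expect_lt(tum$p_value, 0.01)
  expect_true(all(tab$J_true >= 0 & tab$J_true <= 1, na.rm = TRUE))
})

test_that("a cohort of two forces each patch's baseline to be the other", {
  cohort <- make_enr_cohort(2)
  tab <- enrichment_analysis(cohort, seed = 5)
  j12 <- jaccard_components(cohort$binary[[1]], cohort$composite[[2]])
  expect_equal(tab$J_rand[tab$patch_id == "p001"], unname(j12))
})

test_that("single-patch transitions are flagged as missing baselines", {
  cohort <- make_enr_cohort(1)
  expect_warning(tab <- enrichment_analysis(cohort, seed = 2),
                 "single patch")
  expect_true(all(is.na(tab$J_rand)))
})

test_that("label-permuted composites drive median ratios to one", {
  cohort <- make_enr_cohort(200, seed = 8)
  perm <- with_seed2(9, sample(nrow(cohort)))
  cohort$composite <- cohort$composite[perm]
  tab <- enrichment_analysis(cohort, seed = 10)
  agg <- enrichment_summary(tab)
  expect_lt(abs(agg$median_ratio[agg$code == 3] - 1), 0.15)
})
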