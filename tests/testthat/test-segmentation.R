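test_that("DAPI projection is the pixelwise maximum across rounds", {
  sim <- small_sim(seed = 10)
  st <- sim$stack
  proj <- project_dapi(st)
  expect_equal(proj, pmax(st$images[["r1_DAPI"]], st$images[["r2_DAPI"]],
                          st$images[["r3_DAPI"]]))

  single <- st; single$images <- st$images[c("r1_DAPI", "r1_c2")]
  single$meta <- st$meta[c("r1_DAPI", "r1_c2")]
  expect_identical(project_dapi(single), st$images[["r1_DAPI"]])

  zeroed <- st
  zeroed$images[["r2_DAPI"]][] <- 0L
  zeroed$images[["r3_DAPI"]][] <- 0L
  expect_identical(project_dapi(zeroed), st$images[["r1_DAPI"]])

  # constructed fixture: disjoint bright spots from different rounds all
  # survive projection
  a <- matrix(0L, 32, 32); a[5, 5] <- 900L
  b <- matrix(0L, 32, 32); b[20, 25] <- 800L
  st2 <- st
  st2$images <- list(r1_DAPI = a, r2_DAPI = b)
  st2$meta <- st$meta[c("r1_DAPI", "r2_DAPI")]
  pj <- project_dapi(st2)
  expect_equal(pj[5, 5], 900)
  expect_equal(pj[20, 25], 800)
})

test_that("nucleus segmentation resolves single and touching nuclei", {
  # one Gaussian-blurred disk: one label covering >= 90% of the disk
  img <- EBImage::imageData(EBImage::gblur(
    EBImage::Image(disk_image(96, 48, 48, r = 9, value = 3000)), 1.5))
  nuc <- segment_nuclei(img)
  ids <- setdiff(unique(as.vector(nuc$labels)), 0L)
  expect_length(ids, 1)
  truth <- disk_image(96, 48, 48, r = 9, value = 1) > 0
  expect_gte(sum(nuc$labels > 0 & truth) / sum(truth), 0.9)

  # two disks joined by a thin neck separate into two labels
  two <- pmax(disk_image(96, 48, 34, r = 9, value = 3000),
              disk_image(96, 48, 54, r = 9, value = 3000))
  two[47:49, 42:46] <- 1500
  two <- EBImage::imageData(EBImage::gblur(EBImage::Image(two), 1.5))
  nuc2 <- segment_nuclei(two)
  expect_length(setdiff(unique(as.vector(nuc2$labels)), 0L), 2)

  expect_error(segment_nuclei(matrix(0, 64, 64)), "no seeds")
})

test_that("size caps clip nuclei according to cytokeratin class", {
  img <- EBImage::imageData(EBImage::gblur(
    EBImage::Image(disk_image(96, 48, 48, r = 14, value = 3000)), 1.5))
  capped <- segment_nuclei(img, size_cap_ck_pos_px2 = 200,
                           size_cap_ck_neg_px2 = 100,
                           ck_positive = c(FALSE))
  expect_lte(sum(capped$labels > 0), 100)
  capped_pos <- segment_nuclei(img, size_cap_ck_pos_px2 = 200,
                               size_cap_ck_neg_px2 = 100,
                               ck_positive = c(TRUE))
  expect_lte(sum(capped_pos$labels > 0), 200)
  expect_gt(sum(capped_pos$labels > 0), 100)
})

test_that("expand_labels matches the brute-force nearest-label oracle", {
  lab <- matrix(0L, 40, 40)
  lab[10, 10] <- 1L; lab[10, 16] <- 2L; lab[30, 30] <- 3L
  for (d in c(0, 3, 5)) {
    expect_identical(expand_labels(lab, d)$labels, brute_expand(lab, d),
                     info = paste("distance", d))
  }
  # single 1-px label: area equals the brute-force disk pixel count
  solo <- matrix(0L, 33, 33); solo[17, 17] <- 1L
  e <- expand_labels(solo, 5)$labels
  expect_equal(sum(e > 0), sum(brute_expand(solo, 5) > 0))
  # labels 6 px apart expand without overlap, nearest-label assignment
  pair <- matrix(0L, 24, 24); pair[12, 8] <- 1L; pair[12, 14] <- 2L
  expect_identical(expand_labels(pair, 5)$labels, brute_expand(pair, 5))
  # ties go to the smaller label id
  mid <- brute_expand(pair, 5)[12, 11]
  expect_equal(mid, 1L)
  # random multi-label masks agree exactly with the oracle
  set.seed(31)
  for (rep in 1:3) {
    m <- matrix(0L, 48, 48)
    m[cbind(sample(48, 6), sample(48, 6))] <- 1:6
    expect_identical(expand_labels(m, 4)$labels, brute_expand(m, 4))
  }
})

test_that("cell segmentation follows membrane rings and expansion rules", {
  # all membrane-negative: exact reduction to the 5-px expansion
  lab <- matrix(0L, 48, 48); lab[15, 15] <- 1L; lab[33, 30] <- 2L
  memb <- matrix(0, 48, 48)
  cells <- segment_cells(memb, label_mask(lab, "nucleus"),
                         membrane_negative = c(TRUE, TRUE))
  expect_identical(cells$labels, expand_labels(lab, 5)$labels)

  # one nucleus inside a bright membrane ring: boundary lands within 2 px
  # of the ring center-line
  n <- 101; cy <- 51; cx <- 51
  ring <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    rr <- sqrt((i - cy)^2 + (j - cx)^2)
    if (abs(rr - 20) < 2.5) ring[i, j] <- 1000
  }
  nuc <- matrix(0L, n, n)
  nuc[(row(nuc) - cy)^2 + (col(nuc) - cx)^2 <= 36] <- 1L
  cell <- segment_cells(ring, label_mask(nuc, "nucleus"),
                        membrane_negative = c(FALSE),
                        bg_seed_distance_px = 35)
  cellpix <- which(cell$labels == 1L, arr.ind = TRUE)
  radii <- sqrt((cellpix[, 1] - cy)^2 + (cellpix[, 2] - cx)^2)
  expect_lt(max(radii), 22)
  expect_gt(max(radii), 18)

  # membrane-positive cell with no membrane signal stays >= its nucleus
  flat <- matrix(0, 48, 48)
  pos <- segment_cells(flat, label_mask(lab, "nucleus"),
                       membrane_negative = c(FALSE, FALSE))
  expect_true(all(pos$labels[lab > 0] == lab[lab > 0]))
  expect_gte(sum(pos$labels == 1L), sum(lab == 1L))
})

test_that("cytoplasm derivation enforces mask algebra", {
  lab <- matrix(0L, 30, 30); lab[10, 10] <- 1L
  cell <- expand_labels(lab, 5)
  cyt <- derive_cytoplasm(cell, label_mask(lab, "nucleus"))
  expect_equal(sum(cyt$labels > 0), sum(cell$labels > 0) - 1)
  expect_true(all(cyt$labels[lab > 0] == 0L))

  # cell identical to nucleus: empty cytoplasm for that label
  same <- derive_cytoplasm(label_mask(lab, "cell"),
                           label_mask(lab, "nucleus"))
  expect_equal(sum(same$labels > 0), 0)

  # containment violation and label mismatch are rejected
  shifted <- matrix(0L, 30, 30); shifted[20, 20] <- 1L
  expect_error(derive_cytoplasm(label_mask(shifted, "cell"),
                                label_mask(lab, "nucleus")),
               "containment")
  empty <- matrix(0L, 30, 30)
  expect_error(derive_cytoplasm(label_mask(empty, "cell"),
                                label_mask(lab, "nucleus")),
               "mismatch")
})

test_that("mask algebra invariants hold on a full synthetic scene", {
  sim <- small_sim(seed = 12)
  nuc <- sim$truth$nuclei
  memb <- stack_image(sim$stack, 1, "c2")
  cells <- segment_cells(memb, nuc)
  cyt <- derive_cytoplasm(cells, nuc)
  ids <- setdiff(unique(as.vector(nuc$labels)), 0L)
  # nucleus(k) inside cell(k); cytoplasm = cell \ nucleus; no overlap
  expect_true(all(cells$labels[nuc$labels > 0] ==
                  nuc$labels[nuc$labels > 0]))
  expect_true(all((cyt$labels > 0 & nuc$labels > 0) == FALSE))
  recon <- cyt$labels
  recon[nuc$labels > 0] <- nuc$labels[nuc$labels > 0]
  expect_identical(recon, cells$labels)
  # every label is one connected component
  for (k in sample(ids, min(5, length(ids)))) {
    comp <- EBImage::imageData(EBImage::bwlabel(
      EBImage::Image(nuc$labels == k)))
    expect_equal(max(comp), 1)
  }
})

test_that("detection quality holds on non-touching synthetic nuclei", {
  sim <- simulate_image_experiment(sim_image_config(
    shape = c(512L, 512L), n_cells = 150L, rounds = 2L, channels = "c2",
    seed = 13))
  nuc <- segment_nuclei(project_dapi(sim$stack))
  score <- segmentation_f1(nuc, sim$truth$nuclei)
  expect_gte(score$f1, 0.95)
  expect_lte(score$count_error, 0.02)
})
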