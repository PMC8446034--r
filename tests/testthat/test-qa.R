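test_that("aggregate_roi_score handles flat and single-peak maps", {
  sq <- cbind(c(2, 10, 10, 2), c(2, 2, 10, 10))
  m0 <- detection_map(matrix(0, 12, 12), "fracture")
  expect_identical(aggregate_roi_score(m0, sq), 0)
  g <- matrix(0.1, 12, 12); g[5, 5] <- 0.9
  expect_identical(aggregate_roi_score(detection_map(g, "implant"), sq), 0.9)
  # the same peak outside the polygon is not seen
  g2 <- matrix(0.1, 12, 12); g2[1, 1] <- 0.9
  expect_identical(aggregate_roi_score(detection_map(g2, "implant"), sq), 0.1)
})

test_that("cell centres on the polygon boundary are included", {
  g <- matrix(0, 10, 10); g[2, 2] <- 0.7 # centre (x=2, y=2) on the corner
  poly <- cbind(c(2, 6, 6, 2), c(2, 2, 6, 6))
  expect_identical(aggregate_roi_score(detection_map(g, "vcf"), poly), 0.7)
  g3 <- matrix(0, 10, 10); g3[4, 2] <- 0.6 # on the left edge
  expect_identical(aggregate_roi_score(detection_map(g3, "vcf"), poly), 0.6)
})

test_that("aggregate_roi_score rejects degenerate polygons", {
  m <- detection_map(matrix(0.5, 8, 8), "fracture")
  expect_error(aggregate_roi_score(m, cbind(c(1, 2), c(1, 2))), ">= 3")
  expect_error(aggregate_roi_score(m, cbind(c(1, 2, 3), c(1, 2, 3))), "zero area")
  expect_error(aggregate_roi_score(m, cbind(c(20, 25, 25), c(20, 20, 25))),
               "outside")
})

test_that("aggregate_roi_score equals the brute-force oracle on random cases", {
  set.seed(7)
  for (i in 1:60) {
    g <- matrix(runif(24 * 24), 24, 24)
    k <- sample(3:7, 1)
    ang <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)] + runif(k, 0, 0.6)
    cx <- runif(1, 8, 16); cy <- runif(1, 8, 16)
    rad <- runif(k, 3, 8) # star-shaped, possibly non-convex
    poly <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
    expect_equal(aggregate_roi_score(detection_map(g, "fracture"), poly),
                 oracle_roi_max(g, poly))
  }
})

test_that("hip QA excludes on fracture or implant at the inclusive threshold", {
  img <- matrix(100, 16, 16)
  poly <- cbind(c(1, 16, 16, 1), c(1, 1, 16, 16))
  clean <- list(fracture = synthetic_detector(character(), "fracture"),
                implant = synthetic_detector(character(), "implant"))
  q <- hip_qa(img, poly, clean)
  expect_true(q$admissible)
  expect_length(q$reasons, 0)

  imp <- list(fracture = synthetic_detector("implant", "fracture"),
              implant = synthetic_detector("implant", "implant", hit = 1.0))
  q <- hip_qa(img, poly, imp)
  expect_false(q$admissible)
  expect_identical(q$reasons, "implant")

  # score exactly at the threshold is inadmissible (>= convention)
  att <- list(fracture = synthetic_detector("fracture", "fracture", hit = 0.5),
              implant = synthetic_detector(character(), "implant"))
  q <- hip_qa(img, poly, att)
  expect_false(q$admissible)
  expect_identical(q$reasons, "fracture")

  expect_error(hip_qa(img, poly, list(fracture = clean$fracture)),
               "missing detector channel")
})

test_that("neighbour exclusion isolates the deviant vertebra", {
  v <- c(L1 = -1.0, L2 = -1.1, L3 = -0.9, L4 = -1.0)
  expect_length(neighbor_exclusion(v), 0)
  v <- c(L1 = -1.0, L2 = -2.6, L3 = -1.0, L4 = -1.1)
  expect_identical(neighbor_exclusion(v), "L2")
  # deviation exactly at the margin is retained (strict >)
  v <- c(L1 = 0, L2 = 0, L3 = 0, L4 = 1 + 1e-9)
  # leave-one-out mean for L4 is 0; deviation just above 1 -> excluded
  expect_identical(neighbor_exclusion(v), "L4")
  v <- c(L1 = 0, L2 = 0, L3 = 0, L4 = 1)
  expect_length(neighbor_exclusion(v), 0)
  expect_error(neighbor_exclusion(c(L1 = -1)), ">= 2")
})

test_that("adjacent-mean variant reproduces hand-computed neighbour means", {
  v <- c(L1 = -1.0, L2 = -2.6, L3 = -1.0, L4 = -1.1)
  # L2 deviates from mean(L1, L3) = -1.0 by 1.6; L1 deviates from L2 by 1.6
  expect_identical(neighbor_exclusion(v, method = "adjacent"), c("L1", "L2"))
  v2 <- c(L1 = -1.0, L2 = -1.2, L3 = -1.0, L4 = -1.1)
  expect_length(neighbor_exclusion(v2, method = "adjacent"), 0)
})

spine_fixture <- function(flags = rep(list(character()), 4),
                          deform = rep("none", 4),
                          severity = 0.5) {
  lv <- c("L1", "L2", "L3", "L4")
  vert <- lapply(1:4, function(i) {
    spec <- phantom_spec(0.9, deform[i],
                         if (deform[i] == "none") 0 else severity)
    list(landmarks = generate_vertebra_landmarks(spec, level = lv[i]),
         scores = c(implant = if ("implant" %in% flags[[i]]) 0.9 else 0.02,
                    vcf = if ("vcf" %in% flags[[i]]) 0.9 else 0.02))
  })
  names(vert) <- lv
  vert
}

test_that("spine QA passes four clean vertebrae untouched", {
  tt <- c(L1 = -1.2, L2 = -1.0, L3 = -1.4, L4 = -1.1)
  qa <- spine_qa(spine_fixture(), tt)
  expect_true(all(vapply(qa, function(q) q$admissible, logical(1))))
  expect_true(attr(qa, "scan_admissible"))
})

test_that("spine QA traces the three steps on a constructed fixture", {
  # L2 VCF-flagged (step 1), L3 morphometrically biconcave (step 2)
  vert <- spine_fixture(flags = list(character(), "vcf", character(), character()),
                        deform = c("none", "none", "biconcave", "none"))
  tt <- c(L1 = -1.2, L2 = -1.0, L3 = -3.4, L4 = -1.1)
  qa <- spine_qa(vert, tt)
  expect_true(attr(qa, "scan_admissible"))
  expect_identical(qa$L2$reasons, "vcf_detected")
  expect_identical(qa$L3$reasons, "morphometric_deformity")
  expect_true(qa$L1$admissible)
  expect_true(qa$L4$admissible)
  # L3's extreme T-score never reaches step 3: L1/L4 retained
  expect_false("neighbor_deviation" %in% unlist(lapply(qa, `[[`, "reasons")))
})

test_that("fewer than two assessable vertebrae voids the scan", {
  vert <- spine_fixture(flags = list("implant", "implant", "implant", character()))
  tt <- c(L1 = -1, L2 = -1, L3 = -1, L4 = -1)
  qa <- spine_qa(vert, tt)
  expect_false(attr(qa, "scan_admissible"))
  expect_identical(qa$L4$reasons, "too_few_vertebrae")
  expect_false(any(vapply(qa, function(q) q$admissible, logical(1))))
})

test_that("spine QA decisions are independent of input order", {
  vert <- spine_fixture(flags = list(character(), "implant", character(), character()),
                        deform = c("none", "none", "none", "wedge"))
  tt <- c(L1 = -1.2, L2 = -1.0, L3 = -1.4, L4 = -1.1)
  qa1 <- spine_qa(vert, tt)
  perm <- c("L3", "L1", "L4", "L2")
  qa2 <- spine_qa(vert[perm], tt)
  for (v in names(qa1)) {
    expect_identical(qa1[[v]]$reasons, qa2[[v]]$reasons)
    expect_identical(qa1[[v]]$admissible, qa2[[v]]$admissible)
  }
})

test_that("neighbour deviation excludes a vertebra with an outlying T-score", {
  tt <- c(L1 = -1.0, L2 = -2.9, L3 = -1.1, L4 = -0.9)
  qa <- spine_qa(spine_fixture(), tt)
  expect_identical(qa$L2$reasons, "neighbor_deviation")
  expect_true(attr(qa, "scan_admissible"))
})
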