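mk_sample <- function(id, members, group = "NB", qpcr = 1e10) {
  community_sample(id, group, members, qpcr)
}

test_that("incidence matrices weight by relative abundance as stated", {
  m1 <- toy_producer_model()   # reactions EX_glc, EX_ac, GROW, BIOMASS
  m2 <- toy_consumer_model()   # reactions EX_ac, GROW, BIOMASS
  models <- list(producer_A = m1, consumer_B = m2)
  s1 <- mk_sample("s1", c(producer_A = 1))
  s2 <- mk_sample("s2", c(producer_A = 0.3, consumer_B = 0.7))
  w <- build_incidence(list(s1, s2), models, "weighted", "reaction")
  expect_equal(w["s1", "EX_glc"], 1)
  # both members carry EX_ac -> 0.3 + 0.7
  expect_equal(w["s2", "EX_ac"], 1)
  expect_equal(w["s2", "EX_glc"], 0.3)
  b <- build_incidence(list(s1, s2), models, "binary", "reaction")
  expect_true(all(b %in% c(0, 1)))
  expect_equal(b["s2", "EX_glc"], 1)
  expect_error(build_incidence(list(mk_sample("s3", c(ghost = 1))), models),
               "lacking model")
})

test_that("dissimilarities match hand formulas", {
  M <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(0, 0, 1, 1))
  J <- dissimilarity(M, "jaccard")
  expect_equal(unname(diag(J)), rep(0, 3))
  expect_equal(J["a", "b"], 0)
  expect_equal(J["a", "c"], 1)   # disjoint rows
  set.seed(3)
  B <- matrix(rbinom(40, 1, 0.5), 5, 8)
  rownames(B) <- paste0("s", 1:5)
  J2 <- dissimilarity(B, "jaccard")
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(J2[i, j], manual_jaccard(B[i, ], B[j, ]), tolerance = 1e-12)
  }
  W <- rbind(x = c(1, 1), y = c(0, 1))
  expect_equal(dissimilarity(W, "bray_curtis")["x", "y"], 1 / 3)
  A <- matrix(runif(20), 4, 5)
  BC <- dissimilarity(A, "bray_curtis")
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(BC[i, j], manual_bray(A[i, ], A[j, ]), tolerance = 1e-12)
  }
  expect_error(dissimilarity(matrix(c(-1, 1, 1, 1), 2)), "negative")
  expect_error(dissimilarity(matrix(c(0.5, 1, 1, 1), 2), "jaccard"),
               "binary")
})

test_that("classical scaling recovers geometry", {
  # three collinear points: one positive eigenvalue carrying 100% variance
  pts <- c(0, 1, 3)
  D <- as.matrix(stats::dist(pts))
  res <- pcoa(D)
  expect_equal(ncol(res$coordinates), 1L)
  expect_equal(res$percent_variance[1], 100, tolerance = 1e-8)
  # Euclidean-embeddable input: inter-point distances reproduced
  set.seed(5)
  X <- matrix(rnorm(20), 5, 4)
  D2 <- as.matrix(stats::dist(X))
  res2 <- pcoa(D2)
  rec <- as.matrix(stats::dist(res2$coordinates))
  expect_lt(max(abs(rec - D2)), 1e-8)
  # degenerate and malformed inputs
  z <- pcoa(matrix(0, 3, 3))
  expect_true(all(z$coordinates == 0))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("mutual information matches the analytic value and a histogram oracle", {
  x <- c(rep(1, 5), rep(0, 5))
  expect_equal(mutual_information(x, x), log(2), tolerance = 1e-12)
  expect_equal(mutual_information(x, rep(1, 10)), 0)
  set.seed(9)
  for (k in 1:20) {
    a <- rbinom(30, 1, 0.5); b <- rbinom(30, 1, 0.3)
    expect_lt(abs(mutual_information(a, b) - brute_mi(a, b)), 1e-12)
    expect_equal(mutual_information(a, b), mutual_information(b, a))
    expect_gte(mutual_information(a, b), 0)
  }
  # MI vanishes exactly when the 2x2 joint table factorises
  a <- c(1, 1, 0, 0); b <- c(1, 0, 1, 0)
  expect_equal(mutual_information(a, b), 0, tolerance = 1e-12)
  expect_error(mutual_information(numeric(), numeric()), "empty")
  M <- rbind(s1 = x, s2 = x, s3 = 1 - x)
  mm <- mi_matrix(M)
  expect_equal(mm["s1", "s2"], log(2))
  expect_true(isSymmetric(mm))
})

test_that("community metabolic dissimilarity follows the size-adjusted mean", {
  mk_ec_model <- function(id, ecs) {
    gem(id, list(metabolite("a"), metabolite("bm")),
        list(reaction("EX_a", c(a = -1), -10, 10, is_exchange = TRUE),
             reaction("R", c(a = -1, bm = 1), 0, 10, ec_numbers = ecs),
             reaction("BIOMASS", c(bm = -1), 0, 10)),
        "BIOMASS")
  }
  same <- list(mk_ec_model("x", c("1.1.1.1")), mk_ec_model("y", c("1.1.1.1")))
  expect_equal(cmd_score(same)$cmd, 0)
  disjoint <- list(mk_ec_model("x", "1.1.1.1"), mk_ec_model("y", "2.2.2.2"))
  expect_equal(cmd_score(disjoint)$cmd, 1)   # 1 * log2(2)
  # adding a duplicate member: verify against direct recomputation
  three <- c(disjoint, list(mk_ec_model("z", "1.1.1.1")))
  res <- cmd_score(three)
  expect_equal(res$mean_distance, (1 + 0 + 1) / 3, tolerance = 1e-12)
  expect_equal(res$cmd, (2 / 3) * log2(3), tolerance = 1e-12)
  expect_error(cmd_score(disjoint[1]), "at least 2")
})

test_that("metabolic resource overlap uses |intersection| / min cardinality", {
  needs <- function(id, subs) {
    mets <- c(lapply(subs, metabolite), list(metabolite("bm")))
    rxns <- c(lapply(subs, function(s) {
      reaction(paste0("EX_", s), stats::setNames(-1, s), -1000, 1000,
               is_exchange = TRUE)
    }),
    list(reaction("GROW", c(stats::setNames(rep(-1, length(subs)), subs),
                            bm = 1), 0, 1000),
         reaction("BIOMASS", c(bm = -1), 0, 1000)))
    gem(id, mets, rxns, "BIOMASS")
  }
  m_ab <- needs("ab", c("a", "b"))
  m_bc <- needs("bc", c("b", "c"))
  res <- mro_score(list(m_ab, m_bc), c("a", "b", "c"))
  expect_equal(res$mro, 0.5)
  expect_identical(res$minimal_media$ab, c("a", "b"))
  # identical requirements -> 1; disjoint -> 0
  expect_equal(mro_score(list(m_ab, needs("ab2", c("a", "b"))),
                         c("a", "b", "c"))$mro, 1)
  expect_equal(mro_score(list(needs("a1", "a"), needs("c1", "c")),
                         c("a", "b", "c"))$mro, 0)
  # permutation invariance and the duplicated-member property
  trio <- list(m_ab, m_bc, needs("cd", c("c", "d")))
  perm <- mro_score(trio[c(3, 1, 2)], c("a", "b", "c", "d"))
  expect_equal(mro_score(trio, c("a", "b", "c", "d"))$mro, perm$mro)
  with_dup <- c(trio, list(needs("ab_dup", c("a", "b"))))
  expect_gte(mro_score(with_dup, c("a", "b", "c", "d"))$mro,
             mro_score(trio, c("a", "b", "c", "d"))$mro)
  expect_error(mro_score(list(m_ab, needs("x", "x")), c("a", "b", "c")),
               "fails to grow.*x")
})
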