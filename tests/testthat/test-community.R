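# Rarefaction, diversity, the Spearman screen and tpm normalisation.

toy_counts <- function() {
  m <- matrix(c(500, 300, 200,
                900, 50, 50,
                400, 400, 200), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("otu", 1:3)))
  m
}

test_that("rarefaction hits the exact depth, is seed-reproducible and drops shallow sites", {
  m <- toy_counts()
  r1 <- rarefy_counts(m, 600, seed = 4)
  expect_true(all(rowSums(r1) == 600))
  r2 <- rarefy_counts(m, 600, seed = 4)
  expect_identical(r1, r2)
  expect_false(identical(r1, rarefy_counts(m, 600, seed = 5)))
  # depth equal to the site total leaves the site unchanged
  r3 <- rarefy_counts(m, 1000, seed = 1)
  expect_equal(r3[1, ], m[1, ])
  # single-OTU site keeps all reads in that OTU
  one <- matrix(c(0, 800, 0), nrow = 1,
                dimnames = list("s1", paste0("otu", 1:3)))
  expect_equal(as.vector(rarefy_counts(one, 300, seed = 1)), c(0, 300, 0))
  m_low <- rbind(m, shallow = c(10, 5, 5))
  expect_warning(r4 <- rarefy_counts(m_low, 600, seed = 1), "below")
  expect_equal(nrow(r4), 3L)
})

test_that("mean rarefied richness matches the hypergeometric closed form", {
  vec <- c(a = 700, b = 250, c = 50)
  m <- matrix(vec, nrow = 1, dimnames = list("s1", names(vec)))
  obs <- vapply(1:1000, function(i) {
    sum(rarefy_counts(m, 100, seed = i) > 0)
  }, numeric(1))
  expected <- expected_rarefied_richness(vec, 100)
  # 1000 resamples: Monte-Carlo error on the mean is ~0.01
  expect_equal(mean(obs), expected, tolerance = 0.02)
})

test_that("diversity metrics match closed forms and hand arithmetic", {
  uni <- matrix(rep(25, 8), nrow = 1, dimnames = list("u", NULL))
  d <- alpha_diversity(uni)
  expect_equal(d$shannon, log(8))
  expect_equal(d$observed_otus, 8)
  single <- matrix(c(0, 100, 0), nrow = 1)
  d1 <- alpha_diversity(single)
  expect_equal(d1$shannon, 0)
  expect_equal(d1$observed_otus, 1)
  # hand computation on a fixed 4-OTU vector
  p <- c(0.4, 0.3, 0.2, 0.1)
  m4 <- matrix(p * 1000, nrow = 1)
  expect_equal(alpha_diversity(m4)$shannon, -sum(p * log(p)))
  expect_equal(alpha_diversity(m4, base = 2)$shannon,
               -sum(p * log2(p)))
  expect_error(alpha_diversity(matrix(0, 1, 3)), "empty")
})

test_that("spearman screen finds a perfectly rank-correlated OTU among noise", {
  set.seed(9)
  n <- 20
  v <- runif(n)
  m <- matrix(runif(n * 30), nrow = n)
  colnames(m) <- paste0("otu", 1:30)
  m[, 1] <- v + 1  # identical ranks to the variable
  res <- spearman_screen(m, v)
  expect_true(res$hit[res$otu == "otu1"])
  expect_equal(res$rho[res$otu == "otu1"], 1)
  expect_equal(res$p[res$otu == "otu1"], 0)
})

test_that("spearman rho equals the brute-force rank implementation, including ties", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    x <- c(1, 1, sample(1:4, n - 2, replace = TRUE))  # heavy ties
    y <- rnorm(n)
    m <- matrix(x, ncol = 1, dimnames = list(NULL, "otu"))
    res <- suppressWarnings(spearman_screen(m, y, rho_min = 0.99,
                                            q_max = 0.5))
    expect_equal(res$rho, brute_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("screen q-values are BH-monotone and guards fire", {
  set.seed(17)
  m <- matrix(runif(20 * 40), nrow = 20)
  v <- rnorm(20)
  res <- spearman_screen(m, v)
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_error(spearman_screen(m, rep(1, 20)), "constant")
  m2 <- cbind(m, const = 0.5)
  res2 <- spearman_screen(m2, v)
  expect_equal(attr(res2, "excluded"), "const")
  expect_false("const" %in% res2$otu)
})

test_that("tpm normalisation weights by inverse length and rows sum to 1e6", {
  # equal counts, lengths L and 2L -> tpm split 2:1
  counts <- matrix(c(10, 10), nrow = 1)
  tpm <- tpm_normalize(counts, c(100, 200))
  expect_equal(as.vector(tpm), c(2 / 3, 1 / 3) * 1e6)
  # a single expressed gene takes the whole million
  tpm1 <- tpm_normalize(matrix(c(0, 7, 0), nrow = 1), c(50, 100, 150))
  expect_equal(as.vector(tpm1), c(0, 1e6, 0))
  # 3x3 toy against hand arithmetic
  cts <- matrix(c(10, 20, 30,
                  5, 0, 15,
                  8, 8, 8), nrow = 3, byrow = TRUE)
  len <- c(100, 200, 400)
  rate <- sweep(cts, 2, len, "/")
  expect_equal(tpm_normalize(cts, len), rate / rowSums(rate) * 1e6)
  set.seed(23)
  big <- matrix(rpois(50 * 30, 40), nrow = 50)
  expect_equal(rowSums(tpm_normalize(big, runif(30, 200, 2000))),
               rep(1e6, 50), tolerance = 1e-6)
  expect_warning(z <- tpm_normalize(rbind(cts, 0), len), "all-zero")
  expect_equal(unname(z[4, ]), c(0, 0, 0))
})

test_that("grouped expression-rate correlation recovers exact and planted relations", {
  k <- c(0.1, 0.2, 0.3, 0.5, 0.8, 1.2)
  # two genes whose summed tpm is exactly linear in k
  tpm <- cbind(g1 = 3 * k, g2 = 2 * k, g3 = rev(k), g4 = rep(1, 6))
  groups <- c("lin", "lin", "anti", "flat")
  res <- class_rate_correlation(tpm, groups, k)
  expect_equal(res$r[res$group == "lin"], 1)
  expect_lt(res$r[res$group == "anti"], 0)
  expect_true(is.na(res$r[res$group == "flat"]))
  expect_error(class_rate_correlation(tpm[1:3, ], groups, k[1:3]),
               "fewer than")
})
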