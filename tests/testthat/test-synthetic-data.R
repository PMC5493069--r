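families <- list(
  list(name = "corral", gen = function(s) gen_corral(s), m = 32, p = 99),
  list(name = "xor100", gen = function(s) gen_xor100(s), m = 50, p = 99),
  list(name = "parity3p3", gen = function(s) gen_parity3p3(s), m = 64, p = 12),
  list(name = "monk3", gen = function(s) gen_monk3(s), m = 122, p = 6),
  list(name = "madelon_like", gen = function(s) gen_madelon_like(s),
       m = 2400, p = 500)
)

test_that("generators are seed-deterministic and flag every feature", {
  for (fam in families) {
    d1 <- fam$gen(11)
    d2 <- fam$gen(11)
    d3 <- fam$gen(12)
    expect_identical(d1$x, d2$x, label = fam$name)
    expect_identical(d1$labels, d2$labels, label = fam$name)
    expect_false(identical(d1$x, d3$x))
    # relevance bookkeeping covers all p features
    expect_equal(nrow(d1$truth), n_features(d1), label = fam$name)
    expect_setequal(d1$truth$feature, feature_names(d1))
    expect_true(all(d1$truth$flag %in%
                      c("relevant", "redundant", "irrelevant")))
  }
  s1 <- gen_sd("sd1", 3)
  expect_identical(s1$x, gen_sd("sd1", 3)$x)
})

test_that("CorrAL realises its class rule and 75% correlated decoy", {
  d <- gen_corral(seed = 4)
  expect_equal(n_samples(d), 32)
  expect_equal(n_features(d), 99)
  expect_equal(sum(d$truth$flag == "relevant"), 4)
  expect_equal(sum(d$truth$flag == "irrelevant"), 95)
  lab <- as.integer(as.character(d$labels))
  expect_equal(as.integer((d$x$f1 & d$x$f2) | (d$x$f3 & d$x$f4)), lab)
  # f6 agrees with the class on exactly 75% of the 32 samples
  expect_equal(sum(d$x$f6 == lab), 24)
  # the 32 rows enumerate f1..f5 without replacement
  expect_equal(nrow(unique(d$x[, paste0("f", 1:5)])), 32)
})

test_that("XOR-100 label is the XOR of its two relevant features", {
  d <- gen_xor100(seed = 9)
  expect_equal(sum(d$truth$flag == "irrelevant"), 97)
  lab <- as.integer(as.character(d$labels))
  expect_equal(as.integer(xor(d$x$f1, d$x$f2)), lab)
})

test_that("Parity3+3 has parity labels and exact redundant copies", {
  d <- gen_parity3p3(seed = 5)
  lab <- as.integer(as.character(d$labels))
  expect_equal((d$x$f1 + d$x$f2 + d$x$f3) %% 2, lab)
  expect_equal(d$x$r1, d$x$f1)
  expect_equal(d$x$r2, d$x$f2)
  expect_equal(d$x$r3, d$x$f3)
  expect_equal(table(d$truth$flag)[["redundant"]], 3)
  expect_equal(table(d$truth$flag)[["relevant"]], 3)
  expect_equal(table(d$truth$flag)[["irrelevant"]], 6)
})

test_that("Monk3 follows its rule modulo exactly 5% flipped labels", {
  clean <- gen_monk3(seed = 8, noise = FALSE)
  rule <- function(d) {
    as.integer((d$x$f5 == 3 & d$x$f4 == 1) | (d$x$f5 != 4 & d$x$f2 != 3))
  }
  expect_equal(rule(clean), as.integer(as.character(clean$labels)))
  noisy <- gen_monk3(seed = 8, noise = TRUE)
  expect_identical(noisy$x, clean$x)
  flips <- sum(rule(noisy) != as.integer(as.character(noisy$labels)))
  expect_equal(flips, round(0.05 * 122))
  expect_setequal(noisy$truth$feature[noisy$truth$flag == "relevant"],
                  c("f2", "f4", "f5"))
  # samples are distinct points of the MONK attribute space
  expect_equal(nrow(unique(noisy$x)), 122)
})

test_that("SD variants carry the stated group structure", {
  s1 <- gen_sd("sd1", 2)
  expect_equal(n_samples(s1), 75)
  expect_equal(as.integer(table(s1$labels)), rep(25L, 3))
  expect_equal(sum(grepl(":fcr", s1$truth$group)), 20)
  expect_equal(sum(s1$truth$flag == "irrelevant"), 4000)
  expect_equal(attr(s1, "optimal_subset_size"), 2)

  s2 <- gen_sd("sd2", 2)
  expect_equal(sum(grepl(":pcr", s2$truth$group)), 30)
  expect_equal(sum(grepl(":fcr", s2$truth$group)), 10)
  expect_equal(attr(s2, "optimal_subset_size"), 4)

  s3 <- gen_sd("sd3", 2)
  pcr_groups <- unique(na.omit(s3$truth$group[grepl(":pcr", s3$truth$group)]))
  expect_equal(length(pcr_groups), 6)
  expect_equal(sum(grepl(":pcr", s3$truth$group)), 60)
  expect_equal(attr(s3, "optimal_subset_size"), 6)

  expect_error(gen_sd("sd4", 1))

  # a single gene from an FCR group linearly separates the three classes:
  # class-conditional means are 2 apart with sd 0.2
  g <- s1$x[[1]]
  mu <- tapply(g, s1$labels, mean)
  expect_true(min(dist(mu)) > 1.5)
})

test_that("microarray generator yields the requested design", {
  d <- gen_microarray(n_genes = 5000, pde = 0.02, m1 = 50, m2 = 50, seed = 1)
  expect_equal(n_samples(d), 100)
  expect_equal(as.integer(table(d$labels)[c("control", "case")]), c(50L, 50L))
  expect_equal(sum(d$truth$flag == "relevant"), round(0.02 * 5000))
  # half up-, half down-regulated
  expect_equal(sum(d$truth$group == "up", na.rm = TRUE), 50)
  expect_equal(sum(d$truth$group == "down", na.rm = TRUE), 50)
  # up-regulated genes really are higher in cases
  up1 <- d$truth$feature[which(d$truth$group == "up")][1]
  delta <- mean(d$x[[up1]][d$labels == "case"]) -
    mean(d$x[[up1]][d$labels == "control"])
  expect_gt(delta, 1)
  expect_error(gen_microarray(pde = 0), "pde")
  expect_error(gen_microarray(pde = 1), "pde")
  expect_error(gen_microarray(n_genes = 5), "n_genes")
  expect_error(gen_microarray(m1 = 1), "m1")
})

test_that("madelon-like samples sit on a 5-cube with alternating classes", {
  d <- gen_madelon_like(seed = 6)
  expect_equal(n_samples(d), 2400)
  expect_equal(n_features(d), 500)
  expect_equal(sum(d$truth$flag == "irrelevant"), 495)
  expect_equal(sum(d$truth$flag == "relevant"), 5)

  # with jitter and label distortion off, a nearest-vertex classifier on the
  # 5 relevant coordinates is perfect
  clean <- gen_madelon_like(seed = 6, noise_sd = 0, flip_fraction = 0)
  vertices <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
  vclass <- rowSums(vertices > 0) %% 2
  rel <- as.matrix(clean$x[, paste0("rel", 1:5)])
  nearest <- apply(rel, 1, function(s) {
    which.min(colSums((t(vertices) - s)^2))
  })
  expect_equal(vclass[nearest], as.integer(as.character(clean$labels)))

  # default distortion flips 1% of the labels
  noisy_labels <- as.integer(as.character(d$labels))
  clean_geom <- gen_madelon_like(seed = 6, flip_fraction = 0)
  expect_equal(sum(noisy_labels != as.integer(as.character(clean_geom$labels))),
               round(0.01 * 2400))
})

test_that("generate_dataset dispatches by family name", {
  expect_equal(n_features(generate_dataset("corral", 1)), 99)
  expect_identical(generate_dataset("xor100", 3)$x, gen_xor100(3)$x)
  expect_error(generate_dataset("led", 1), "unknown")
})
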