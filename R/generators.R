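# Seeded generators for the classic feature-selection benchmark families.
# Each returns an rgife_dataset whose `truth` table flags every feature as
# relevant / redundant / irrelevant (plus a group id where redundancy is
# organised in groups), so selections can be scored against ground truth.

make_truth <- function(feature, flag, group = NA_character_) {
  data.frame(feature = feature, flag = flag, group = group,
             stringsAsFactors = FALSE)
}

#' CorrAL benchmark dataset
#'
#' 32 samples, 99 binary features. The class is `(f1 & f2) | (f3 & f4)`;
#' `f5` is irrelevant and `f6` agrees with the class on exactly 75% of the
#' samples (the correlated decoy). The remaining 93 features are random
#' binary noise. The 32 rows enumerate all combinations of `f1..f5`.
#'
#' @param seed integer seed; fully determines the output.
#' @return An [rgife_dataset()] with ground-truth flags (`f1..f4` relevant).
#' @export
gen_corral <- function(seed = 1) {
  with_seed(seed, {
    grid <- expand.grid(f1 = 0:1, f2 = 0:1, f3 = 0:1, f4 = 0:1, f5 = 0:1)
    grid <- grid[sample.int(32), , drop = FALSE]
    rownames(grid) <- NULL
    label <- as.integer((grid$f1 & grid$f2) | (grid$f3 & grid$f4))
    # f6 matches the class except on exactly 8 of 32 rows (75% agreement)
    flip <- sample.int(32, 8)
    f6 <- label
    f6[flip] <- 1L - f6[flip]
    noise <- matrix(sample(0:1, 32 * 93, replace = TRUE), nrow = 32)
    colnames(noise) <- paste0("irr", seq_len(93))
    x <- cbind(grid, f6 = f6, as.data.frame(noise))
    truth <- make_truth(colnames(x),
                        ifelse(colnames(x) %in% paste0("f", 1:4),
                               "relevant", "irrelevant"))
    rgife_dataset(x, label, truth)
  })
}

#' XOR-100 benchmark dataset
#'
#' 50 samples, 99 binary features; the class is `f1 XOR f2` and the other 97
#' features are random binary noise.
#'
#' @inheritParams gen_corral
#' @return An [rgife_dataset()]; `f1`, `f2` flagged relevant.
#' @export
gen_xor100 <- function(seed = 1) {
  with_seed(seed, {
    m <- 50
    repeat {
      f1 <- sample(0:1, m, replace = TRUE)
      f2 <- sample(0:1, m, replace = TRUE)
      label <- as.integer(xor(f1, f2))
      if (min(table(factor(label, levels = 0:1))) >= 2) break
    }
    noise <- matrix(sample(0:1, m * 97, replace = TRUE), nrow = m)
    colnames(noise) <- paste0("irr", seq_len(97))
    x <- data.frame(f1 = f1, f2 = f2, noise, check.names = FALSE)
    truth <- make_truth(colnames(x),
                        c("relevant", "relevant", rep("irrelevant", 97)))
    rgife_dataset(x, label, truth)
  })
}

#' Parity3+3 benchmark dataset
#'
#' 64 samples, 12 binary features: three relevant bits whose parity defines
#' the class, three redundant copies of those bits, and six irrelevant bits.
#' The rows enumerate all 2^6 combinations of the relevant bits and the first
#' three irrelevant bits; the remaining irrelevant bits are random.
#'
#' @inheritParams gen_corral
#' @return An [rgife_dataset()] with relevant/redundant/irrelevant flags.
#' @export
gen_parity3p3 <- function(seed = 1) {
  with_seed(seed, {
    grid <- expand.grid(f1 = 0:1, f2 = 0:1, f3 = 0:1,
                        i1 = 0:1, i2 = 0:1, i3 = 0:1)
    grid <- grid[sample.int(64), , drop = FALSE]
    rownames(grid) <- NULL
    label <- (grid$f1 + grid$f2 + grid$f3) %% 2L
    x <- data.frame(grid[, 1:3],
                    r1 = grid$f1, r2 = grid$f2, r3 = grid$f3,
                    grid[, 4:6],
                    i4 = sample(0:1, 64, replace = TRUE),
                    i5 = sample(0:1, 64, replace = TRUE),
                    i6 = sample(0:1, 64, replace = TRUE))
    truth <- make_truth(colnames(x),
                        c(rep("relevant", 3), rep("redundant", 3),
                          rep("irrelevant", 6)),
                        c(paste0("b", 1:3), paste0("b", 1:3),
                          rep(NA_character_, 6)))
    rgife_dataset(x, label, truth)
  })
}

#' Monk3 benchmark dataset
#'
#' 122 samples drawn without replacement from the 432 points of the MONK
#' attribute space (f1,f2,f4 in 1..3, f3,f6 in 1..2, f5 in 1..4). The class
#' rule is `(f5 == 3 & f4 == 1) | (f5 != 4 & f2 != 3)`; 5% of labels
#' (`round(0.05 * 122) = 6`) are flipped when `noise = TRUE`, giving the
#' dataset its noisy character.
#'
#' @inheritParams gen_corral
#' @param noise flip 5% of the labels (default `TRUE`).
#' @return An [rgife_dataset()] with categorical features; `f2`, `f4`, `f5`
#'   flagged relevant.
#' @export
gen_monk3 <- function(seed = 1, noise = TRUE) {
  with_seed(seed, {
    grid <- expand.grid(f1 = 1:3, f2 = 1:3, f3 = 1:2,
                        f4 = 1:3, f5 = 1:4, f6 = 1:2)
    rows <- sample.int(nrow(grid), 122)
    g <- grid[rows, , drop = FALSE]
    rownames(g) <- NULL
    label <- as.integer((g$f5 == 3 & g$f4 == 1) | (g$f5 != 4 & g$f2 != 3))
    if (noise) {
      nflip <- round(0.05 * 122)
      flip <- sample.int(122, nflip)
      label[flip] <- 1L - label[flip]
    }
    x <- as.data.frame(lapply(g, function(col) factor(col)),
                       optional = TRUE)
    truth <- make_truth(colnames(x),
                        ifelse(colnames(x) %in% c("f2", "f4", "f5"),
                               "relevant", "irrelevant"))
    rgife_dataset(x, label, truth)
  })
}

#' SD1-SD3 benchmark datasets
#'
#' Three-class datasets with 75 samples (25 per class) and 4000 irrelevant
#' genes plus groups of ten mutually redundant relevant genes. SD1 has two
#' full-class-relevant (FCR) groups; SD2 one FCR group and three
#' partial-class-relevant (PCR) groups; SD3 six PCR groups. FCR genes take a
#' distinct class mean for every class, PCR genes separate one class from the
#' rest; within a group genes share the template up to Gaussian noise
#' (sd 0.2). Irrelevant genes are standard Gaussian. The optimal signature is
#' one gene per group (sizes 2 / 4 / 6), exposed as the `optimal_subset_size`
#' attribute.
#'
#' @param variant `"sd1"`, `"sd2"` or `"sd3"`.
#' @inheritParams gen_corral
#' @return An [rgife_dataset()]; relevant genes carry their group id and an
#'   FCR/PCR role in the truth table's `group` column (`"g<k>:fcr"` /
#'   `"g<k>:pcr"`).
#' @export
gen_sd <- function(variant = c("sd1", "sd2", "sd3"), seed = 1) {
  variant <- match.arg(variant)
  roles <- switch(variant,
                  sd1 = rep("fcr", 2),
                  sd2 = c("fcr", rep("pcr", 3)),
                  sd3 = rep("pcr", 6))
  with_seed(seed, {
    classes <- rep(paste0("c", 1:3), each = 25)
    n_groups <- length(roles)
    # class-mean templates: FCR groups get a permutation of (0, 2, 4);
    # PCR groups single out one class (mean 2) against the rest (mean 0)
    fcr_templates <- list(c(0, 2, 4), c(4, 0, 2), c(2, 4, 0))
    cols <- list()
    truth_rows <- list()
    fcr_i <- 0
    pcr_i <- 0
    for (g in seq_len(n_groups)) {
      if (roles[g] == "fcr") {
        fcr_i <- fcr_i + 1
        mu <- fcr_templates[[(fcr_i - 1) %% 3 + 1]]
      } else {
        pcr_i <- pcr_i + 1
        mu <- c(0, 0, 0)
        mu[(pcr_i - 1) %% 3 + 1] <- 2
      }
      base <- mu[as.integer(factor(classes))]
      block <- matrix(stats::rnorm(75 * 10, mean = base, sd = 0.2),
                      nrow = 75)
      nm <- sprintf("%s_g%d_%02d", roles[g], g, seq_len(10))
      colnames(block) <- nm
      cols[[g]] <- block
      truth_rows[[g]] <- make_truth(nm, "relevant",
                                    sprintf("g%d:%s", g, roles[g]))
    }
    irr <- matrix(stats::rnorm(75 * 4000), nrow = 75)
    colnames(irr) <- sprintf("irr%04d", seq_len(4000))
    x <- as.data.frame(cbind(do.call(cbind, cols), irr))
    truth <- rbind(do.call(rbind, truth_rows),
                   make_truth(colnames(irr), "irrelevant"))
    d <- rgife_dataset(x, classes, truth)
    attr(d, "optimal_subset_size") <- n_groups
    d
  })
}

#' Two-condition synthetic microarray dataset
#'
#' Structural emulation of a two-condition (control vs case) microarray
#' simulation: each gene has a baseline log2-scale mean drawn from
#' Normal(7, 1.5); `round(pde * n_genes)` genes are differentially expressed
#' in the case group, half shifted up and half down by 1.5; all measurements
#' carry within-group Gaussian noise with sd 0.4. Not bit-compatible with any
#' external simulator.
#'
#' @param n_genes number of genes (>= 10).
#' @param pde fraction of differentially expressed genes, in (0, 1).
#' @param m1,m2 number of control / case samples (>= 2 each).
#' @inheritParams gen_corral
#' @return An [rgife_dataset()] with classes `control` / `case`; DE genes are
#'   flagged relevant with group `"up"` or `"down"`.
#' @export
gen_microarray <- function(n_genes = 5000, pde = 0.02, m1 = 50, m2 = 50,
                           seed = 1) {
  if (n_genes < 10) stop("n_genes must be >= 10")
  if (!(pde > 0 && pde < 1)) stop("pde must be strictly between 0 and 1")
  if (m1 < 2 || m2 < 2) stop("m1 and m2 must both be >= 2")
  with_seed(seed, {
    m <- m1 + m2
    n_de <- round(pde * n_genes)
    if (n_de < 1) stop("pde too small: no gene would be differentially ",
                       "expressed at n_genes = ", n_genes)
    de_idx <- sample.int(n_genes, n_de)
    n_up <- ceiling(n_de / 2)
    up_idx <- de_idx[seq_len(n_up)]
    down_idx <- setdiff(de_idx, up_idx)
    mu <- stats::rnorm(n_genes, mean = 7, sd = 1.5)
    shift <- numeric(n_genes)
    shift[up_idx] <- 1.5
    shift[down_idx] <- -1.5
    case <- c(rep(0, m1), rep(1, m2))
    x <- sapply(seq_len(n_genes), function(j) {
      stats::rnorm(m, mean = mu[j] + shift[j] * case, sd = 0.4)
    })
    colnames(x) <- sprintf("gene%05d", seq_len(n_genes))
    flag <- rep("irrelevant", n_genes)
    flag[de_idx] <- "relevant"
    grp <- rep(NA_character_, n_genes)
    grp[up_idx] <- "up"
    grp[down_idx] <- "down"
    labels <- c(rep("control", m1), rep("case", m2))
    rgife_dataset(as.data.frame(x), labels,
                  make_truth(colnames(x), flag, grp))
  })
}

#' Madelon-like benchmark dataset
#'
#' 2400 samples, 500 continuous features. Five relevant features place every
#' sample near one of the 32 vertices of a 5-dimensional hypercube (vertex
#' coordinates +/-1); classes alternate over vertices (vertex parity), 75
#' samples per vertex. Of the 495 remaining features, 250 are standard
#' Gaussian noise and 245 are random linear combinations of the relevant
#' features plus noise; all 495 are flagged irrelevant. A fraction of labels
#' is flipped to distort the problem.
#'
#' @inheritParams gen_corral
#' @param noise_sd Gaussian jitter around the hypercube vertices (default
#'   0.3); 0 puts every sample exactly on its vertex.
#' @param flip_fraction fraction of labels flipped at random (default 0.01);
#'   0 disables the distortion.
#' @return An [rgife_dataset()]; the 5 hypercube coordinates are flagged
#'   relevant.
#' @export
gen_madelon_like <- function(seed = 1, noise_sd = 0.3, flip_fraction = 0.01) {
  with_seed(seed, {
    m <- 2400
    vertices <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5)))
    vclass <- rowSums(vertices > 0) %% 2L  # alternating over the hypercube
    assignment <- sample(rep(seq_len(32), each = 75))
    rel <- vertices[assignment, , drop = FALSE] +
      matrix(stats::rnorm(m * 5, sd = noise_sd), nrow = m)
    colnames(rel) <- paste0("rel", 1:5)
    label <- vclass[assignment]
    if (flip_fraction > 0) {
      nflip <- round(flip_fraction * m)
      flip <- sample.int(m, nflip)
      label[flip] <- 1L - label[flip]
    }
    gauss <- matrix(stats::rnorm(m * 250), nrow = m)
    colnames(gauss) <- sprintf("noise%03d", seq_len(250))
    combo_w <- matrix(stats::rnorm(5 * 245), nrow = 5)
    combos <- rel %*% combo_w + matrix(stats::rnorm(m * 245, sd = 0.5),
                                       nrow = m)
    colnames(combos) <- sprintf("combo%03d", seq_len(245))
    x <- as.data.frame(cbind(rel, gauss, combos))
    truth <- make_truth(colnames(x),
                        c(rep("relevant", 5), rep("irrelevant", 495)))
    rgife_dataset(x, label, truth)
  })
}

#' Dispatch a generator by family name
#'
#' @param family one of `"corral"`, `"xor100"`, `"parity3p3"`, `"monk3"`,
#'   `"sd1"`, `"sd2"`, `"sd3"`, `"microarray"`, `"madelon_like"`.
#' @param seed integer seed.
#' @param ... family-specific parameters forwarded to the generator
#'   (e.g. `n_genes`, `pde`, `m1`, `m2` for `"microarray"`).
#' @return An [rgife_dataset()].
#' @export
generate_dataset <- function(family, seed = 1, ...) {
  switch(family,
         corral = gen_corral(seed),
         xor100 = gen_xor100(seed),
         parity3p3 = gen_parity3p3(seed),
         monk3 = gen_monk3(seed, ...),
         sd1 = gen_sd("sd1", seed),
         sd2 = gen_sd("sd2", seed),
         sd3 = gen_sd("sd3", seed),
         microarray = gen_microarray(seed = seed, ...),
         madelon_like = gen_madelon_like(seed, ...),
         stop("unknown generator family: ", family))
}
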