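write_tree_file <- function(text) {
  f <- withr::local_tempfile(fileext = ".nwk", .local_envir = parent.frame())
  writeLines(text, f)
  f
}

test_that("Newick reading validates structure, branch lengths and labels", {
  tr <- read_newick(write_tree_file("(A:1,B:1);"))
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(unname(diag(ape::vcv.phylo(tr))), c(1, 1))

  tr2 <- read_newick(write_tree_file("((A:1,B:1):1,C:2);"))
  expect_equal(ape::vcv.phylo(tr2)["A", "B"], 1)  # MRCA depth 1 from root

  expect_error(read_newick(write_tree_file("((A:1,B:1")), "cannot parse")
  expect_error(read_newick(write_tree_file("((A:1,B:1):1,C);")),
               "missing branch length")
  expect_error(read_newick(write_tree_file("((A:1,A:1):1,C:2);")),
               "duplicate tip")
})

test_that("grafting inserts a sister tip at the stated divergence, preserving ultrametry", {
  tr <- read_newick(write_tree_file("(A:3,B:3);"))
  g <- graft_taxon(tr, "C", "A", 1)
  expect_true(ape::is.ultrametric(g, tol = 1e-9))
  C <- ape::vcv.phylo(g)
  expect_equal(C["C", "C"], 3)       # root-to-tip depth preserved
  expect_equal(C["A", "C"], 2)       # A and C diverged 1 Myr ago
  expect_error(graft_taxon(tr, "C", "A", 5), "exceeds terminal branch")
  expect_error(graft_taxon(tr, "A", "B", 1), "already present")
})

test_that("a missing baboon species grafts at 1.99 Myr onto its sister lineage", {
  papio <- read_newick(write_tree_file(
    "(((Papio_cynocephalus:4.2,Papio_anubis:4.2):3.8,Theropithecus_gelada:8):12,Macaca_mulatta:20);"))
  g <- graft_taxon(papio, "Papio_kindae", "Papio_cynocephalus", 1.99)
  expect_true(ape::is.ultrametric(g, tol = 1e-9))
  C <- ape::vcv.phylo(g)
  depth <- C["Papio_cynocephalus", "Papio_cynocephalus"]
  expect_equal(C["Papio_kindae", "Papio_cynocephalus"], depth - 1.99,
               tolerance = 1e-9)
})

test_that("grafting then pruning the new tip restores the distance matrix", {
  set.seed(21)
  tr <- simulate_tree(8)
  g <- graft_taxon(tr, "extra", "sp03",
                   0.5 * domstyle:::.terminal_branch(tr, "sp03"))
  back <- prune_taxon(g, "extra")
  d0 <- ape::cophenetic.phylo(tr)
  d1 <- ape::cophenetic.phylo(back)[rownames(d0), colnames(d0)]
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("phylogenetic covariance encodes shared ancestry scaled by lambda", {
  tr <- read_newick(write_tree_file("((A:1,B:1):1,C:2);"))
  C1 <- phylo_covariance(tr, c("A", "B", "C"), lambda = 1)
  expect_equal(unname(C1), matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3))
  C0 <- phylo_covariance(tr, c("A", "B", "C"), lambda = 0)
  expect_equal(unname(C0), diag(c(2, 2, 2)))
  expect_error(phylo_covariance(tr, c("A", "Z")), "not in tree: Z")
  # order follows the supplied species vector
  expect_equal(rownames(phylo_covariance(tr, c("C", "A"))), c("C", "A"))
})

test_that("random Yule-tree covariances are positive semi-definite and ultrametric", {
  set.seed(31)
  for (rep in 1:10) {
    tr <- simulate_tree(sample(5:20, 1))
    C <- phylo_covariance(tr)
    expect_silent(chol(C + 1e-10 * diag(nrow(C))))
    expect_equal(unname(diag(C)), rep(40, nrow(C)), tolerance = 1e-8)
  }
})

test_that("PGLS with identity covariance reproduces ordinary least squares", {
  set.seed(41)
  n <- 15
  X <- cbind(1, runif(n), runif(n))
  y <- X %*% c(1, 2, -1) + rnorm(n)
  fit <- pgls_fit(y, X, diag(n))
  ols <- lm(y ~ X - 1)
  expect_equal(fit$coefficients$beta, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-8)
})

test_that("PGLS equals OLS on Cholesky-whitened data for arbitrary covariance", {
  set.seed(51)
  for (rep in 1:10) {
    n <- 12
    tr <- simulate_tree(n)
    C <- phylo_covariance(tr)
    X <- cbind(1, rnorm(n), rnorm(n))
    y <- rnorm(n, sd = 3)
    fit <- pgls_fit(y, X, C)
    L <- t(chol(C))
    wfit <- lm(solve(L, y) ~ solve(L, X) - 1)
    expect_equal(fit$coefficients$beta, unname(coef(wfit)), tolerance = 1e-8)
    expect_equal(fit$coefficients$p,
                 unname(summary(wfit)$coefficients[, 4]), tolerance = 1e-8)
    # p-values are invariant to rescaling the covariance
    fit2 <- pgls_fit(y, X, 7.7 * C)
    expect_equal(fit2$coefficients$p, fit$coefficients$p, tolerance = 1e-10)
    expect_equal(fit2$coefficients$beta, fit$coefficients$beta, tolerance = 1e-10)
  }
})

test_that("PGLS agrees with nlme::gls under a Brownian correlation structure", {
  skip_if_not_installed("nlme")
  set.seed(61)
  n <- 14
  tr <- simulate_tree(n)
  d <- data.frame(species_id = tr$tip.label, x = rnorm(n))
  d$y <- 0.5 - 0.8 * d$x + as.vector(t(chol(phylo_covariance(tr))) %*% rnorm(n)) * 0.1
  fit <- pgls(y ~ x, d, tr)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corBrownian(1, tr, form = ~species_id))
  expect_equal(coef(fit), coef(g), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-6)
})

test_that("the species trait table joins index, repertoires and group sizes", {
  idx <- data.frame(species_id = c("s1", "s2", "s3"),
                    mean_dii = c(0.1, 0.2, 0.3), mean_counter = c(5, 10, 15),
                    mean_intensity = c(30, 20, 10),
                    z_dii = c(-1, 0, 1), z_counter = c(-1, 0, 1),
                    z_intensity = c(-1, 0, 1), composite = c(-1, 0, 1))
  rep_tab <- data.frame(species_id = c("s1", "s2"),
                        total_calls = c(10, 20), hierarchy_calls = c(3, 1))
  meta <- data.frame(group_id = paste0("g", 1:4),
                     species_id = c("s1", "s1", "s2", "s3"),
                     group_size = c(20, 30, 10, 8))
  expect_message(st <- species_table(idx, rep_tab, meta), "dropping species.*s3")
  expect_equal(nrow(st), 2L)
  expect_equal(st$group_size[st$species_id == "s1"], 25)
  expect_equal(st$log_hierarchy, log10(c(3, 1) + 1))
  expect_error(species_table(idx[0, ], rep_tab, meta), "empty join")
})
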