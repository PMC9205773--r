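susc_table <- function(stats) {
  data.frame(structure = names(stats), med_abs_d = unname(stats),
             max_p_large = NA_real_, stringsAsFactors = FALSE)
}

test_that("ROI selection takes the top k with deterministic ties, or a threshold", {
  st <- susc_table(c(a = 0.5, b = 2, c = 1, d = 2, e = 0.1))
  roi <- select_roi(st, k = 3)
  expect_identical(roi$structures, c("b", "d", "c"))  # tie b/d by name
  expect_identical(select_roi(st, k = 5)$structures, c("b", "d", "c", "a", "e"))
  thr <- select_roi(st, threshold = 0.9)
  expect_setequal(thr$structures, c("b", "c", "d"))
  expect_error(select_roi(st, k = 9), "exceeds")
  expect_error(select_roi(st, threshold = 5), "no structure")
})

test_that("fold change is the ROI mean over the whole-brain mean", {
  em <- matrix(1, 3, 10, dimnames = list(paste0("g", 1:3), paste0("r", 1:10)))
  fc <- fold_change(em, paste0("r", 1:2))
  expect_true(all(fc$fc == 1))
  # gene with 5 in each of 2 ROI structures, 0 in the other 8: FC = 5/1
  em2 <- em
  em2["g2", ] <- c(5, 5, rep(0, 8))
  fc2 <- fold_change(em2, c("r1", "r2"))
  expect_equal(fc2$fc[fc2$gene == "g2"], 5)
  expect_equal(fc2$rank[fc2$gene == "g2"], 1)
  # relabelling structures together with the ROI leaves FC unchanged
  perm <- sample(10)
  em3 <- em2[, perm]
  fc3 <- fold_change(em3, colnames(em2)[1:2])
  expect_equal(fc3$fc[order(fc3$gene)], fc2$fc[order(fc2$gene)])
  # global rescaling invariance
  fc4 <- fold_change(em2 * 7.3, c("r1", "r2"))
  expect_equal(fc4$fc, fc2$fc)
  # zero rows are dropped with a warning
  em5 <- em2; em5["g3", ] <- 0
  expect_warning(fc5 <- fold_change(em5, c("r1", "r2")), "dropped")
  expect_false("g3" %in% fc5$gene)
})

test_that("target sets are top-n by fold change with nested robustness sweep", {
  set.seed(2)
  em <- matrix(rlnorm(200 * 8), 200, 8,
               dimnames = list(sprintf("g%03d", 1:200), paste0("r", 1:8)))
  fc <- fold_change(em, c("r1", "r2"))
  expect_setequal(target_set(fc, 200), fc$gene)
  expect_identical(target_set(fc, 10), fc$gene[1:10])
  sweep3 <- target_set_sweep(fc, c(50, 100, 150))
  expect_true(all(sweep3[["50"]] %in% sweep3[["100"]]))
  expect_true(all(sweep3[["100"]] %in% sweep3[["150"]]))
  expect_error(target_set(fc, 300), "exceeds")
})

test_that("hypergeometric p matches exact enumeration", {
  bg <- paste0("g", 1:20)
  res <- hypergeom_enrich(bg[1:10], list(t1 = bg[c(1:5)]), bg)
  expect_equal(res$p, 3003 / 184756, tolerance = 1e-12)
  expect_equal(res$overlap, 5)
  # target = background makes every term's p 1
  res2 <- hypergeom_enrich(bg, list(t1 = bg[1:5], t2 = bg[6:7]), bg)
  expect_true(all(res2$p == 1))
  # random small instances against the combinatorial oracle
  set.seed(6)
  for (i in 1:15) {
    N <- sample(10:30, 1)
    bg <- paste0("g", 1:N)
    term <- sample(bg, sample(2:(N - 2), 1))
    target <- sample(bg, sample(2:(N - 2), 1))
    res <- hypergeom_enrich(target, list(t = term), bg)
    expect_equal(res$p,
                 oracle_hypergeom(res$overlap, length(term), N,
                                  length(target)),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_enrich("x", list(t = "x"), character(0)),
               "background")
  expect_error(hypergeom_enrich("zz", list(t = "g1"), paste0("g", 1:5)),
               "within background")
})

test_that("enrichment p-values are super-uniform for random targets", {
  set.seed(11)
  bg <- paste0("g", 1:400)
  sets <- list(t1 = sample(bg, 60), t2 = sample(bg, 100))
  ps <- replicate(100, {
    hypergeom_enrich(sample(bg, 80), sets, bg)$p
  })
  expect_gt(mean(ps > 0.05), 0.85)
})

test_that("KS comparison matches a brute-force ECDF oracle", {
  fc <- structure(data.frame(gene = paste0("g", 1:6),
                             fc = c(1, 2, 3, 4, 5, 6), rank = 1:6),
                  class = c("fold_change_table", "data.frame"))
  expect_equal(ks_compare(fc, paste0("g", 1:6))$D, 0)
  expect_equal(ks_compare(fc, paste0("g", 1:3), against = "complement")$D, 1)
  set.seed(13)
  for (i in 1:10) {
    n <- 40
    fcr <- structure(data.frame(gene = paste0("g", 1:n), fc = rnorm(n),
                                rank = 1:n),
                     class = c("fold_change_table", "data.frame"))
    term <- sample(fcr$gene, 12)
    D <- ks_compare(fcr, term, against = "complement")$D
    x <- fcr$fc[fcr$gene %in% term]; y <- fcr$fc[!fcr$gene %in% term]
    grid <- sort(c(x, y))
    D_oracle <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
    expect_equal(D, D_oracle, tolerance = 1e-12)
  }
})

test_that("trajectory clustering recovers four archetypes and their representatives", {
  atlas <- generate_expression_atlas(
    250, structures = "r1", roi_structures = "r1",
    noise_sd = 0.1, seed = 17)
  cl <- cluster_trajectories(atlas$development, k_range = 2:8, seed = 1)
  expect_equal(cl$k, 4)
  expect_gt(rand_index(unname(cl$cluster[names(atlas$archetype)]),
                       as.integer(factor(atlas$archetype))), 0.95)
  # representatives belong to their own clusters
  for (i in seq_along(cl$representatives))
    expect_equal(unname(cl$cluster[cl$representatives[i]]), i)
})

test_that("forced k skips the elbow and duplication leaves centroids unchanged", {
  atlas <- generate_expression_atlas(
    120, structures = "r1", roi_structures = "r1", noise_sd = 0.1, seed = 18)
  cl4 <- cluster_trajectories(atlas$development, k_range = 4, seed = 2)
  expect_equal(cl4$k, 4)
  dev2 <- rbind(atlas$development,
                `rownames<-`(atlas$development,
                             paste0(rownames(atlas$development), "_dup")))
  cl_dup <- cluster_trajectories(dev2, k_range = 4, seed = 2)
  ord <- function(C) C[order(C[, 1]), ]
  expect_equal(ord(cl_dup$centroids), ord(cl4$centroids), tolerance = 1e-6)
  # constant trajectories are dropped with a warning
  dev3 <- atlas$development
  dev3[1, ] <- 5
  expect_warning(cluster_trajectories(dev3, k_range = 4, seed = 2), "constant")
})

test_that("the elbow rule recovers the generating cluster count at low noise", {
  hits <- 0; total <- 0
  for (k_true in 2:5) for (s in 1:3) {
    set.seed(1000 * k_true + s)
    protos <- matrix(rnorm(k_true * 8, sd = 2), k_true, 8)
    genes <- matrix(NA, 40 * k_true, 8)
    for (g in seq_len(nrow(genes)))
      genes[g, ] <- protos[(g - 1) %% k_true + 1, ] + rnorm(8, 0, 0.15)
    rownames(genes) <- sprintf("g%03d", seq_len(nrow(genes)))
    colnames(genes) <- paste0("t", 1:8)
    # scan from k = 1 so the smallest generating k is an interior elbow
    cl <- cluster_trajectories(genes, k_range = 1:8, seed = s)
    total <- total + 1
    hits <- hits + (cl$k == k_true)
  }
  expect_gte(hits / total, 0.8)
})
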