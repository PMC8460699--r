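mk_table <- function(m, kind = "point_mutation") {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("p", seq_len(ncol(m)))
  omics_table(m, kind)
}

test_that("gene selection applies the prevalence thresholds with correct strictness", {
  m <- matrix(0L, 3, 100)
  m[1, 1:3] <- 1L   # prevalence 0.03
  m[2, 1:5] <- 1L   # prevalence 0.05
  rownames(m) <- c("at3", "at5", "zero")
  colnames(m) <- paste0("p", 1:100)
  tab <- omics_table(m, "point_mutation")

  sel <- select_genes(tab, 0.03, strict = FALSE)   # point-mutation rule
  expect_true("at3" %in% sel$gene)
  sel_cna <- select_genes(tab, 0.05, strict = TRUE)  # CNA rule
  expect_false("at5" %in% sel_cna$gene)
  expect_false("zero" %in% select_genes(tab, 0.01)$gene)

  # sorted by descending prevalence, ties by name
  m2 <- rbind(b = c(1L, 1L, 0L, 0L), a = c(1L, 1L, 0L, 0L), c = c(1L, 1L, 1L, 0L))
  colnames(m2) <- paste0("p", 1:4)
  sel2 <- select_genes(omics_table(m2, "point_mutation"), 0.1)
  expect_identical(sel2$gene, c("c", "a", "b"))

  # monotone: raising the threshold never adds genes
  withr::with_seed(1, {
    m3 <- matrix(rbinom(20 * 50, 1, 0.2), 20, 50)
  })
  tab3 <- mk_table(m3)
  for (th in c(0.05, 0.1, 0.2, 0.4)) {
    lo <- select_genes(tab3, th)$gene
    hi <- select_genes(tab3, th + 0.1)$gene
    expect_true(all(hi %in% lo))
  }
})

test_that("alteration binarization follows the discrete-call conventions", {
  cna <- mk_table(matrix(c(-2L, -1L, 0L, 1L, 2L), 5, 1), "cna")
  expect_identical(as.vector(binarize_alterations(cna)$values),
                   c(1L, 1L, 0L, 1L, 1L))
  expect_identical(as.vector(binarize_alterations(cna, "level2")$values),
                   c(1L, 0L, 0L, 0L, 1L))
  expect_error(binarize_alterations(mk_table(matrix(0.5, 1, 1), "cna")),
               "discrete")
  pm <- mk_table(matrix(c(0, 3, 1), 3, 1), "point_mutation")
  expect_identical(as.vector(binarize_alterations(pm)$values), c(0L, 1L, 1L))
})

test_that("pathway activity is the oncogene/suppressor-weighted mean, binarized at zero", {
  one <- function(u, role) {
    tab <- mk_table(matrix(u, 1, 1, dimnames = list("G", "p1")), "expression")
    pathway_activity(tab, data.frame(pathway = "pw", gene = "G", role = role))
  }
  a <- one(2.0, "oncogene")
  expect_equal(a$v[1, 1], 2.0)
  expect_identical(a$l[1, 1], 1L)
  b <- one(2.0, "suppressor")
  expect_equal(b$v[1, 1], -2.0)
  expect_identical(b$l[1, 1], 0L)
  z <- one(0, "oncogene")
  expect_identical(z$l[1, 1], 0L)   # v exactly 0 is inactivated

  # two members: (3 - 1) / 2 = 1
  tab <- mk_table(matrix(c(3, 1), 2, 1, dimnames = list(c("ON", "SU"), "p1")),
                  "expression")
  defs <- data.frame(pathway = "pw", gene = c("ON", "SU"),
                     role = c("oncogene", "suppressor"))
  expect_equal(pathway_activity(tab, defs)$v[1, 1], 1.0)

  expect_error(pathway_activity(tab, data.frame(pathway = "ghost",
                                                gene = "NOPE",
                                                role = "oncogene")),
               "ghost")
  expect_error(pathway_activity(mk_table(matrix(1, 1, 1), "point_mutation"),
                                defs),
               "expression or cna")
})

test_that("pathway activity matches a brute-force double loop on random tables", {
  withr::with_seed(42, {
    genes <- paste0("G", 1:20)
    u <- matrix(rnorm(20 * 50), 20, 50, dimnames = list(genes, paste0("p", 1:50)))
    defs <- data.frame(
      pathway = rep(c("pw1", "pw2", "pw3"), times = c(7, 6, 7)),
      gene = sample(genes, 20),
      role = sample(c("oncogene", "suppressor"), 20, replace = TRUE))
  })
  act <- pathway_activity(omics_table(u, "expression"), defs)

  for (p in unique(defs$pathway)) {
    mem <- defs[defs$pathway == p, ]
    for (s in colnames(u)) {
      v <- 0
      for (k in seq_len(nrow(mem))) {
        w <- if (mem$role[k] == "oncogene") 1 else -1
        v <- v + w * u[mem$gene[k], s]
      }
      v <- v / nrow(mem)
      expect_equal(act$v[s, p], v, tolerance = 1e-9)
      expect_identical(act$l[s, p], as.integer(v > 0))
    }
  }
})

test_that("pathway activity antisymmetry properties hold", {
  withr::with_seed(7, {
    u <- matrix(rnorm(6 * 10), 6, 10,
                dimnames = list(paste0("G", 1:6), paste0("p", 1:10)))
  })
  defs <- data.frame(pathway = "pw", gene = paste0("G", 1:6),
                     role = rep(c("oncogene", "suppressor"), 3))
  flipped <- defs
  flipped$role <- ifelse(defs$role == "oncogene", "suppressor", "oncogene")
  v0 <- pathway_activity(omics_table(u, "expression"), defs)$v
  # negating u and flipping all weights leaves v unchanged
  v1 <- pathway_activity(omics_table(-u, "expression"), flipped)$v
  expect_equal(v1, v0, tolerance = 1e-12)
  # negating u alone negates v
  v2 <- pathway_activity(omics_table(-u, "expression"), defs)$v
  expect_equal(v2, -v0, tolerance = 1e-12)
})

test_that("label tables assemble task columns with per-task positive counts", {
  expect_identical(ncol(make_label_table(tasks = data.frame())), 1L)

  withr::with_seed(3, {
    om <- generate_omics(1000, data.frame(gene = "MUT5", prevalence = 0.05))
  })
  tasks <- data.frame(name = "MUT5_point", type = "gene_point", target = "MUT5")
  lab <- make_label_table(mutations = binarize_alterations(om$mutation),
                          tasks = tasks)
  pos <- attr(lab, "positives")[["MUT5_point"]]
  expect_gte(pos, 30L)   # binomial 99% interval for n = 1000, p = 0.05
  expect_lte(pos, 70L)

  # pathway column passes through l exactly
  defs <- data.frame(pathway = "pw", gene = c("A", "B"),
                     role = c("oncogene", "suppressor"))
  withr::with_seed(4, {
    u <- matrix(rnorm(2 * 20), 2, 20, dimnames = list(c("A", "B"), paste0("p", 1:20)))
  })
  act <- pathway_activity(omics_table(u, "expression"), defs)
  lab2 <- make_label_table(activities_expr = act,
                           tasks = data.frame(name = "pw_expr",
                                              type = "pathway_expr",
                                              target = "pw"))
  expect_identical(lab2$pw_expr, unname(act$l[lab2$patient_id, "pw"]))

  expect_warning(make_label_table(activities_expr = act,
                                  tasks = data.frame(name = "pw_expr",
                                                     type = "pathway_expr",
                                                     target = "pw"),
                                  cache_patients = paste0("p", 1:10)),
                 "absent from the feature cache")
})
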