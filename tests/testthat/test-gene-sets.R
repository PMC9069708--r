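test_that("common-list ranking uses the min of the two fold changes", {
  a <- deg_stub(c("g1", "g2", "g3"), c("up", "up", "up"),
                log2fc = c(3, 2, 1.2))
  b <- deg_stub(c("g1", "g2", "g3"), c("up", "up", "ns"),
                log2fc = c(1, 2, 4))
  top <- rank_top_common(a, b, "up", n = 200)
  expect_equal(top$gene_symbol, c("g2", "g1"))   # min ranks: 2 > 1
  expect_equal(top$rank_metric, c(2, 1))
  # g3 excluded: ns in b; no padding to n
  expect_equal(nrow(top), 2)
  # symmetric as a set
  top_ba <- rank_top_common(b, a, "up", n = 200)
  expect_setequal(top$gene_symbol, top_ba$gene_symbol)
  expect_error(rank_top_common(a, b, "up", n = 0), class = "config_error")
})

test_that("concordant subset keeps order and drops discordant genes", {
  ref <- deg_stub(c("x", "y", "z"), c("up", "down", "up"))
  expect_equal(concordant_subset(c("z", "x", "y"), ref, "up"),
               c("z", "x"))
  expect_equal(concordant_subset(c("x", "y"), deg_stub(character(0),
                                                       character(0)),
                                 "up"),
               character(0))
  # planted bookkeeping: a list sharing exactly k genes with the
  # reference's up-set yields a subset of size k
  set.seed(1)
  shared <- sprintf("s%d", 1:7)
  ref2 <- deg_stub(c(shared, "other1", "other2"),
                   c(rep("up", 7), "down", "ns"))
  lst <- c(shared, sprintf("only%d", 1:5))
  expect_length(concordant_subset(lst, ref2, "up"), 7)
})

test_that("exclusive lists exclude genes changed in the other cell type", {
  this <- deg_stub(c("a", "b", "c"), c("up", "up", "up"),
                   log2fc = c(1.1, 3, 2))
  other <- deg_stub(c("a", "b", "c"), c("up", "ns", "not_expressed"))
  ex <- exclusive_top(this, other, "up", n = 50)
  expect_equal(ex$gene_symbol, c("b", "c"))      # ranked by |log2fc|
  # empty other table: plain top-n
  ex2 <- exclusive_top(this, deg_stub(character(0), character(0)), "up",
                       n = 2)
  expect_equal(ex2$gene_symbol, c("b", "c"))
  # exclusive and common lists are disjoint for the same direction
  common <- rank_top_common(this, other, "up", n = 50)
  expect_length(intersect(ex$gene_symbol, common$gene_symbol), 0)
})

test_that("exclusive lists on disjoint planted sets recover the planted sets", {
  a_genes <- sprintf("a%d", 1:6); b_genes <- sprintf("b%d", 1:4)
  all_genes <- c(a_genes, b_genes, "null1", "null2")
  deg_a <- deg_stub(all_genes,
                    c(rep("up", 6), rep("ns", 4), "ns", "ns"))
  deg_b <- deg_stub(all_genes,
                    c(rep("ns", 6), rep("up", 4), "ns", "ns"))
  expect_setequal(exclusive_top(deg_a, deg_b, "up", 50)$gene_symbol,
                  a_genes)
  expect_setequal(exclusive_top(deg_b, deg_a, "up", 50)$gene_symbol,
                  b_genes)
})

test_that("hypergeometric enrichment matches closed form and enumeration", {
  u <- letters[1:10]
  res <- hypergeom_enrichment(letters[1:4], letters[1:5], u)
  expect_equal(res$overlap, 4)
  expect_equal(res$p_value, 5 / 210)           # C(5,4)C(5,0)/C(10,4)

  expect_equal(hypergeom_enrichment(letters[1:3], u, u)$p_value, 1)
  expect_error(hypergeom_enrichment("a", "b", character(0)),
               class = "config_error")
  expect_error(hypergeom_enrichment("z", "a", u), class = "config_error")

  # brute-force enumeration oracle on random small universes
  set.seed(7)
  for (i in 1:20) {
    uni <- sample(letters, sample(6:12, 1))
    cat_set <- sample(uni, sample(1:length(uni), 1))
    hits <- sample(uni, sample(1:4, 1))
    skip <- length(cat_set) == length(uni) &&
      length(intersect(hits, cat_set)) < length(hits)
    if (skip) next
    expect_equal(hypergeom_enrichment(hits, cat_set, uni)$p_value,
                 hyper_enum_p(hits, cat_set, uni), tolerance = 1e-12)
  }
})

test_that("category-table enrichment BH-adjusts across categories", {
  ann <- tibble::tibble(
    gene_symbol = c("a", "b", "c", "d", "e", "f", "a", "b"),
    category = c(rep("oxidative stress", 6), rep("autophagy", 2)))
  res <- enrich_categories(c("a", "b"), ann,
                           universe = c(letters[1:10]))
  expect_setequal(res$category, c("oxidative stress", "autophagy"))
  expect_equal(res$fdr, bh_fdr(res$p_value))
  aut <- res[res$category == "autophagy", ]
  expect_equal(aut$overlap, 2L)
  expect_equal(aut$p_value,
               hypergeom_enrichment(c("a", "b"), c("a", "b"),
                                    letters[1:10])$p_value)
})

test_that("the shipped annotation fixture drives the enrichment surface", {
  path <- system.file("extdata", "annotations_synthetic.tsv",
                      package = "cochleaging")
  res <- enrich_categories(c("Foxo3", "Igf1r", "Sirt6"), path)
  top <- res$category[1]
  expect_equal(top, "aging/longevity")
  expect_equal(res$overlap[res$category == "aging/longevity"], 3L)
})
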