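test_that("shared-gene projection counts set intersections", {
  tab <- disease_gene_table(
    disease = c("D1", "D1", "D2", "D2"),
    gene = c("g1", "g2", "g2", "g3")
  )
  proj <- disease_projection(tab)
  expect_equal(nrow(proj), 1)
  expect_equal(proj$weight, 1)
  expect_equal(proj$disease_a, "D1")
})

test_that("disjoint diseases with no cross edges project to nothing", {
  tab <- disease_gene_table(c("D1", "D2"), c("g1", "g2"))
  expect_equal(nrow(disease_projection(tab)), 0)
  ppi <- interactome(tibble::tibble(a = "g1", b = "g9"))
  expect_equal(nrow(disease_projection(tab, "interacting", ppi)), 0)
})

test_that("interacting mode needs a ppi graph and counts cross pairs", {
  tab <- disease_gene_table(c("D1", "D1", "D2"), c("g1", "g2", "g3"))
  expect_error(disease_projection(tab, "interacting"),
               class = "sgpnet_argument_error")
  ppi <- interactome(tibble::tibble(a = c("g1", "g2"), b = c("g3", "g3")))
  proj <- disease_projection(tab, "interacting", ppi)
  expect_equal(proj$weight, 2)   # g1-g3 and g2-g3
})

test_that("random projections equal the nested-loop oracle and obey bounds", {
  for (seed in c(3, 13, 23)) {
    tab <- random_disease_table(5, 40, seed)
    proj <- disease_projection(tab)
    oracle <- oracle_disease_weights(tab)
    got <- as.data.frame(proj[, c("disease_a", "disease_b", "weight")])
    ord <- function(d) d[order(d$disease_a, d$disease_b), ]
    expect_equal(ord(got), ord(oracle), ignore_attr = TRUE)
    # no self-edges; symmetry is structural (each unordered pair appears once)
    expect_true(all(proj$disease_a != proj$disease_b))
    expect_true(all(proj$disease_a < proj$disease_b))
    # weight bounded by the smaller gene set
    sets <- lapply(split(tab$gene, tab$disease), unique)
    for (i in seq_len(nrow(proj))) {
      expect_lte(proj$weight[i],
                 min(lengths(sets[c(proj$disease_a[i], proj$disease_b[i])])))
    }
  }
})

test_that("pathway containers validate species classes and endpoints", {
  expect_error(
    pathway_definition("p", data.frame(id = "a", species = "metabolite")),
    class = "sgpnet_input_error"
  )
  expect_error(
    pathway_definition(
      "p", data.frame(id = "a", species = "protein"),
      data.frame(class = "prot_prot", from = "a", to = "zzz",
                 sign = "activation")
    ),
    "zzz", class = "sgpnet_input_error"
  )
  # class must agree with endpoint species
  expect_error(
    pathway_definition(
      "p", data.frame(id = c("a", "b"), species = c("signal", "gene")),
      data.frame(class = "prot_prot", from = "a", to = "b",
                 sign = "activation")
    ),
    class = "sgpnet_input_error"
  )
})

test_that("crosstalk reports shared members, ranked and deterministic", {
  q <- pathway_definition("q", data.frame(id = c("a", "b", "c"),
                                          species = "protein"))
  cat1 <- pathway_definition("other", data.frame(id = c("c", "d"),
                                                 species = "protein"))
  ct <- pathway_crosstalk(q, list(cat1))
  expect_equal(ct$shared_n, 1)
  expect_equal(ct$shared_members[[1]], "c")

  disjoint <- pathway_definition("far", data.frame(id = "z",
                                                   species = "protein"))
  expect_equal(nrow(pathway_crosstalk(q, list(disjoint))), 0)
})

test_that("crosstalk on random catalogs matches the exhaustive oracle", {
  pws <- random_pathways(10, 30, 11)
  ct <- pathway_crosstalk(pws[[1]], pws)
  oracle <- oracle_crosstalk(pws[[1]], pws)
  expect_equal(nrow(ct), length(oracle))
  # same partners with the same shared members, and counts rank the output
  o_names <- vapply(oracle, `[[`, character(1), "pathway")
  for (i in seq_len(nrow(ct))) {
    j <- match(ct$pathway[i], o_names)
    expect_identical(ct$shared_members[[i]], oracle[[j]]$shared)
  }
  expect_true(all(diff(ct$shared_n) <= 0))
  # every reported member really is in both pathways
  for (i in seq_len(nrow(ct))) {
    partner <- pws[[match(ct$pathway[i], vapply(pws, `[[`, "", "name"))]]
    expect_true(all(ct$shared_members[[i]] %in% pws[[1]]$members$id))
    expect_true(all(ct$shared_members[[i]] %in% partner$members$id))
  }
  # re-running is byte-stable
  again <- pathway_crosstalk(pws[[1]], pws)
  expect_identical(ct, again)
})

test_that("duplicate catalog names are an input error", {
  q <- pathway_definition("q", data.frame(id = "a", species = "gene"))
  p1 <- pathway_definition("same", data.frame(id = "a", species = "gene"))
  expect_error(pathway_crosstalk(q, list(p1, p1)),
               class = "sgpnet_input_error")
})

test_that("pathway YAML round-trips through read/write", {
  pw <- psen1_pathway_synthetic()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_pathway(pw, path)
  back <- read_pathway(path)
  expect_equal(back$name, pw$name)
  expect_equal(back$members, pw$members)
  expect_equal(back$interactions, pw$interactions)
})

test_that("disease-gene TSV reader applies pair uniqueness", {
  tab <- read_disease_gene_table(read_fixture("disease_genes_example.tsv"))
  expect_s3_class(tab, "disease_gene_table")
  expect_false(any(duplicated(tab[, c("disease", "gene")])))
  proj <- disease_projection(tab)
  expect_true(all(c("Alzheimer disease", "Frontotemporal dementia") %in%
                    c(proj$disease_a, proj$disease_b)))
})
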