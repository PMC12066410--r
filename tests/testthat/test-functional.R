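nsaf_db <- function(lengths, taxa = NULL) {
  n <- length(lengths)
  tibble::tibble(
    accession = sprintf("p%d", seq_len(n)),
    sequence = strrep("A", lengths),
    taxon_code = taxa %||% rep("sp1", n),
    length = as.integer(lengths)
  )
}

test_that("NSAF normalizes by length over the microbial scope", {
  db <- nsaf_db(c(100, 200, 150, 120), taxa = c("sp1", "sp1", "HOST", "DIET"))
  quant <- dplyr::bind_rows(
    quant_row("S1", "p1", 10, 1, "sp1"),
    quant_row("S1", "p2", 10, 1, "sp1"),
    quant_row("S1", "p3", 500, 1, "HOST"),
    quant_row("S1", "p4", 500, 1, "DIET")
  )
  out <- nsaf(quant, db)
  vals <- setNames(out$nsaf_pct, out$accession)
  # SAF = (0.1, 0.05) -> (66.67, 33.33); host/diet excluded entirely
  expect_equal(unname(vals["p1"]), 200 / 3, tolerance = 1e-9)
  expect_equal(unname(vals["p2"]), 100 / 3, tolerance = 1e-9)
  expect_false(any(c("p3", "p4") %in% out$accession))
  expect_equal(sum(out$nsaf_pct), 100, tolerance = 1e-9)

  # single microbial protein gets 100%
  solo <- nsaf(quant_row("S1", "p1", 3, 1, "sp1"), db)
  expect_equal(solo$nsaf_pct, 100)

  # doubling all lengths leaves NSAF% unchanged (pure ratio)
  db2 <- dplyr::mutate(db, length = length * 2L)
  expect_equal(nsaf(quant, db2)$nsaf_pct, out$nsaf_pct, tolerance = 1e-12)

  bad <- dplyr::mutate(db, length = c(0L, 200L, 150L, 120L))
  expect_error(nsaf(quant, bad), "Zero-length")
})

test_that("ambiguous, low-quality and unbinned proteins stay in the NSAF denominator", {
  db <- nsaf_db(c(100, 100, 100), taxa = c("sp1", "AMBIGUOUS", "LOWQ"))
  quant <- dplyr::bind_rows(
    quant_row("S1", "p1", 10, 1, "sp1"),
    quant_row("S1", "p2", 10, 1, "AMBIGUOUS"),
    quant_row("S1", "p3", 20, 1, "LOWQ")
  )
  out <- nsaf(quant, db)
  expect_equal(nrow(out), 3)
  expect_equal(sum(out$nsaf_pct), 100, tolerance = 1e-9)
  expect_equal(out$nsaf_pct[out$accession == "p1"], 25, tolerance = 1e-9)
})

test_that("orgNSAF is confined to one species and invariant to the rest", {
  db <- nsaf_db(c(100, 100, 50), taxa = c("spA", "spA", "spB"))
  quant <- dplyr::bind_rows(
    quant_row("S1", "p1", 30, 1, "spA"),
    quant_row("S1", "p2", 10, 1, "spA"),
    quant_row("S1", "p3", 99, 1, "spB")
  )
  a <- org_nsaf(quant, db, "spA")
  expect_equal(sum(a$nsaf_pct), 100, tolerance = 1e-9)
  expect_equal(setNames(a$nsaf_pct, a$accession), c(p1 = 75, p2 = 25),
               tolerance = 1e-9)

  # perturbing species B leaves A's profile untouched
  quant2 <- quant
  quant2$spectral_count[3] <- 9999L
  expect_equal(org_nsaf(quant2, db, "spA"), a)

  solo <- org_nsaf(quant, db, "spB")
  expect_equal(solo$nsaf_pct, 100)
  expect_error(org_nsaf(quant, db, "spZ"), "no quantified proteins")
})

test_that("consensus annotation applies the provenance precedence", {
  tools <- tibble::tibble(
    accession = rep(c("X", "Y", "Z", "W"), each = 2),
    tool = rep(c("t1", "t2"), 4),
    label = c("urease", "urease",          # X: curated anchor
              "urease", "urease",          # Y: same signature as X
              "gh18", "mannosidase",       # Z: tools disagree
              "enolase", "enolase")        # W: consensus, no anchor
  )
  manual <- tibble::tibble(accession = "X", label = "urease [curated]")
  res <- consensus_annotate(tools, manual)
  res <- res[match(c("X", "Y", "Z", "W"), res$accession), ]
  expect_equal(res$provenance, c("manual", "extrapolated", "unannotated",
                                 "consensus"))
  # the curated name is extrapolated to Y via the shared signature
  expect_equal(res$label, c("urease [curated]", "urease [curated]",
                            NA, "enolase"))

  expect_error(
    consensus_annotate(tools, tibble::tibble(accession = c("X", "X"),
                                             label = c("a", "b"))),
    "Conflicting"
  )

  # conflicting anchors for one signature block extrapolation
  manual2 <- tibble::tibble(accession = c("X", "Y"),
                            label = c("urease A", "urease B"))
  tools2 <- dplyr::bind_rows(
    tools,
    tibble::tibble(accession = "V", tool = c("t1", "t2"),
                   label = c("urease", "urease"))
  )
  res2 <- consensus_annotate(tools2, manual2)
  v <- res2[res2$accession == "V", ]
  expect_equal(v$provenance, "consensus")  # falls back to tool consensus
})

test_that("rollup conserves 100% via the unannotated feature", {
  db <- nsaf_db(c(100, 100, 100, 100))
  quant <- dplyr::bind_rows(
    quant_row("S1", "p1", 10, 1, "sp1"),
    quant_row("S1", "p2", 20, 1, "sp1"),
    quant_row("S1", "p3", 30, 1, "sp1"),
    quant_row("S1", "p4", 40, 1, "sp1")
  )
  nt <- nsaf(quant, db)
  ann <- tibble::tibble(
    accession = c("p1", "p2", "p3"),
    broad_category = c("amino acid metabolism", "amino acid metabolism",
                       "glycan degradation"),
    gh_family = c(NA, NA, "GH18"),
    pul_id = c(NA, NA, "PUL01")
  )
  r <- rollup(nt, ann, "broad")
  vals <- setNames(r$nsaf_pct, r$feature)
  expect_equal(unname(vals["amino acid metabolism"]), 30, tolerance = 1e-9)
  expect_equal(unname(vals["glycan degradation"]), 30, tolerance = 1e-9)
  expect_equal(unname(vals["unannotated"]), 40, tolerance = 1e-9)
  expect_equal(sum(r$nsaf_pct), 100, tolerance = 1e-9)

  # single-category degenerate case
  ann_all <- tibble::tibble(accession = sprintf("p%d", 1:4),
                            broad_category = "gene expression")
  r_all <- rollup(nt, ann_all, "broad")
  expect_equal(r_all$nsaf_pct, 100, tolerance = 1e-9)

  # a protein in two PULs violates the partition requirement
  ann_dup <- dplyr::bind_rows(ann, tibble::tibble(
    accession = "p3", broad_category = NA, gh_family = NA, pul_id = "PUL02"
  ))
  expect_error(rollup(nt, ann_dup, "pul"), "multiple pul")
})

test_that("amino-acid pathway rollup and panels sum the right members", {
  db <- nsaf_db(c(100, 100, 100, 100))
  quant <- dplyr::bind_rows(
    quant_row("S1", "p1", 10, 1, "sp1"),  # urease (degradation, ammonia)
    quant_row("S1", "p2", 20, 1, "sp1"),  # tryptophanase (degradation, ammonia)
    quant_row("S1", "p3", 30, 1, "sp1"),  # glutamine synthetase (synthesis)
    quant_row("S1", "p4", 40, 1, "sp1")   # unmapped
  )
  nt <- nsaf(quant, db)
  ann <- tibble::tibble(
    accession = c("p1", "p2", "p3"),
    enzyme_name = c("urease", "tryptophanase", "glutamine synthetase")
  )
  aa_map <- default_aa_pathway_map()
  r <- amino_acid_class_rollup(nt, ann, aa_map)
  deg <- sum(r$nsaf_pct[r$direction == "degradation"])
  expect_equal(deg, 30, tolerance = 1e-9)
  expect_equal(sum(r$nsaf_pct[r$direction == "synthesis"]), 30, tolerance = 1e-9)

  # synthesis-only map: no degradation mass
  synth_map <- dplyr::filter(aa_map, direction == "synthesis")
  r2 <- amino_acid_class_rollup(nt, ann, synth_map)
  expect_equal(sum(r2$nsaf_pct[r2$direction == "degradation"]), 0)

  # urease panel sums only urease proteins
  expect_equal(enzyme_panel(nt, ann, "urease")$nsaf_pct, 10, tolerance = 1e-9)
  # ammonia panel: urease + tryptophanase (both degradation, ammonia products)
  expect_equal(ammonia_panel(nt, ann, aa_map)$nsaf_pct, 30, tolerance = 1e-9)

  bad_map <- dplyr::mutate(aa_map, direction = replace(direction, 1, "sideways"))
  expect_error(amino_acid_class_rollup(nt, ann, bad_map), "sideways")
})

test_that("synthetic annotations feed every rollup level", {
  comm <- clean_community(4, seed = 13)
  cat <- generate_protein_catalog(comm, proteins_per_species = 6, seed = 13)
  anns <- generate_annotations(cat, seed = 13)
  psms <- simulate_psm_table(comm, cat, depth = 3000, seed = 13)
  quant <- count_spectra(filter_psms(psms), cat$database)
  nt <- nsaf(quant, cat$database)
  for (lvl in c("broad", "detailed", "enzyme", "gh_family", "pul")) {
    r <- rollup(nt, anns$annotations, lvl)
    tot <- r |> dplyr::group_by(sample_id) |> dplyr::summarise(s = sum(nsaf_pct))
    expect_equal(tot$s, rep(100, nrow(tot)), tolerance = 1e-9)
  }
  cons <- consensus_annotate(anns$tool_labels, anns$manual)
  expect_true(all(cons$provenance %in%
                    c("manual", "extrapolated", "consensus", "unannotated")))
})
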