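test_that("bin quality screening applies both acceptance tiers", {
  bins <- tibble::tibble(
    bin_id = c("b1", "b2", "b3", "b4", "b5"),
    completeness = c(60, 40, 40, 50, 30),
    contamination = c(5, 3, 8, 9, 4)
  )
  res <- classify_bins(bins)
  expect_equal(
    res$decision,
    c("ACCEPT_SPECIES",   # >50 complete, <10 contaminated
      "ACCEPT_LOWQ_TIER", # >30 complete, <5 contaminated
      "REJECT",           # fails both
      "REJECT",           # thresholds are strict: 50 is not >50
      "REJECT")           # 30 is not >30
  )
  expect_error(
    classify_bins(tibble::tibble(bin_id = "x", completeness = -1,
                                 contamination = 0)),
    "\\[0, 100\\]"
  )
})

test_that("sequence identity equals the alignment oracle", {
  set.seed(42)
  # substitution-only pairs: the optimal alignment is unambiguous
  for (i in 1:10) {
    s <- random_seq(60)
    t <- mutate_seq(s, sample(0:15, 1))
    expect_equal(seq_identity(s, t), nw_identity_oracle(s, t), tolerance = 1e-12)
  }
  # length-mismatched pair exercises gaps and the shorter-length denominator
  a <- random_seq(40)
  b <- paste0(substr(a, 1, 30), random_seq(10))
  expect_equal(seq_identity(a, b), nw_identity_oracle(a, b), tolerance = 1e-12)
  expect_equal(seq_identity("MKTAYR", "MKTAYR"), 1)
})

test_that("binned/unbinned merge drops redundant sequences at 90% identity", {
  set.seed(1)
  base <- random_seq(100)
  binned <- tibble::tibble(accession = "bin1", sequence = base)

  identical_seq <- base
  near <- mutate_seq(base, 8)    # 92% identity -> redundant
  far <- mutate_seq(base, 15)    # 85% identity -> retained
  unrelated <- random_seq(100)

  unbinned <- tibble::tibble(
    accession = c("u1", "u2", "u3", "u4"),
    sequence = c(identical_seq, near, far, unrelated)
  )
  out <- merge_binned_unbinned(binned, unbinned, identity_threshold = 0.90)
  expect_setequal(out$accession, c("u3", "u4"))
  expect_true(all(out$taxon_code == "UNBINNED"))

  expect_error(merge_binned_unbinned(binned, unbinned, identity_threshold = 0),
               "identity_threshold")
})

test_that("merge decisions equal the exhaustive alignment oracle on toys", {
  set.seed(99)
  binned <- tibble::tibble(
    accession = sprintf("b%d", 1:8),
    sequence = replicate(8, random_seq(sample(40:80, 1)))
  )
  unbinned <- tibble::tibble(
    accession = sprintf("u%d", 1:20),
    sequence = c(
      vapply(binned$sequence[1:10 %% 8 + 1][1:10],
             function(s) mutate_seq(s, sample(0:12, 1)), character(1)),
      replicate(10, random_seq(sample(40:80, 1)))
    )
  )
  out <- merge_binned_unbinned(binned, unbinned, identity_threshold = 0.90)
  oracle_keep <- vapply(unbinned$sequence, function(u) {
    !any(vapply(binned$sequence,
                function(b) nw_identity_oracle(u, b) >= 0.90, logical(1)))
  }, logical(1))
  expect_setequal(out$accession, unbinned$accession[oracle_keep])
})

test_that("species codes follow the ambiguity and low-quality rules", {
  seq_a <- random_seq(30, seed = 2)
  seq_b <- random_seq(30, seed = 3)
  seq_c <- random_seq(30, seed = 4)
  seq_d <- random_seq(30, seed = 5)
  proteins <- tibble::tibble(
    accession = c("p1", "p2", "p2b", "p3", "p4"),
    sequence = c(seq_a, seq_b, seq_b, seq_c, seq_d),
    bin_id = c("binA", "binA", "binB", "binC", "binD")
  )
  bin_map <- tibble::tibble(
    bin_id = c("binA", "binB", "binC", "binD"),
    species_group_id = c("sg1", "sg2", "sg3", "sg4"),
    decision = c("ACCEPT_SPECIES", "ACCEPT_SPECIES", "ACCEPT_LOWQ_TIER",
                 "REJECT")
  )
  db <- assign_species_codes(proteins, bin_map)
  codes <- setNames(db$taxon_code, db$accession)
  expect_equal(unname(codes["p1"]), "sg1")
  expect_equal(unname(codes["p2"]), "AMBIGUOUS")  # same sequence, two groups
  expect_equal(unname(codes["p3"]), "LOWQ")
  expect_false("p4" %in% db$accession)            # rejected bin dropped

  # species precedence over LOWQ for a sequence in both tiers
  both <- dplyr::bind_rows(
    proteins[1, ],
    tibble::tibble(accession = "p1lq", sequence = seq_a, bin_id = "binC")
  )
  expect_message(db2 <- assign_species_codes(both, bin_map), "species code kept")
  expect_equal(db2$taxon_code, "sg1")

  expect_error(
    assign_species_codes(
      tibble::tibble(accession = "x", sequence = "MK", bin_id = "nope"),
      bin_map
    ),
    "unknown bins"
  )
})

test_that("reference relabeling recodes only matches at or above 95%", {
  set.seed(7)
  ref_seq <- random_seq(100)
  db <- tibble::tibble(
    accession = sprintf("p%d", 1:5),
    sequence = c(ref_seq,                 # identical -> recoded
                 mutate_seq(ref_seq, 4),  # 96% -> recoded
                 mutate_seq(ref_seq, 6),  # 94% -> unchanged
                 random_seq(100),
                 random_seq(80)),
    taxon_code = "sg1",
    length = c(100L, 100L, 100L, 100L, 80L)
  )
  reference <- tibble::tibble(accession = "BT_ref", sequence = ref_seq)
  out <- relabel_by_reference(db, reference, "BT", identity_threshold = 0.95)
  expect_equal(out$taxon_code, c("BT", "BT", "sg1", "sg1", "sg1"))

  expect_error(relabel_by_reference(db, reference, "HOST"), "reserved")
  expect_error(relabel_by_reference(db, reference[0, ], "BT"), "non-empty")
})

test_that("host/diet appending clusters redundancy and is idempotent", {
  set.seed(8)
  db <- tibble::tibble(accession = "m1", sequence = random_seq(50),
                       taxon_code = "sg1", length = 50L)
  host_seq <- random_seq(60)
  host <- tibble::tibble(accession = c("h1", "h2"),
                         sequence = c(host_seq, host_seq))
  out <- append_host_diet(db, host = host)
  expect_equal(sum(out$taxon_code == "HOST"), 1)
  expect_equal(sum(out$taxon_code == "DIET"), 0)

  # 10 diet sequences with 3 identical pairs -> 7 representatives
  uniq <- replicate(7, random_seq(40))
  diet <- tibble::tibble(
    accession = sprintf("d%d", 1:10),
    sequence = c(uniq, uniq[1:3])
  )
  out2 <- append_host_diet(db, host = host, diet = diet)
  expect_equal(sum(out2$taxon_code == "DIET"), 7)

  # idempotence: appending the same inputs again changes nothing
  out3 <- append_host_diet(out2, host = host, diet = diet)
  expect_equal(out3, out2)

  # accession collision is renamed with a source prefix
  clash <- tibble::tibble(accession = "m1", sequence = random_seq(45))
  expect_message(out4 <- append_host_diet(db, host = clash), "Renaming")
  expect_true("host_m1" %in% out4$accession)

  expect_error(append_host_diet(db), "At least one")
})

test_that("full database build partitions codes and round-trips FASTA", {
  set.seed(9)
  proteins <- tibble::tibble(
    accession = sprintf("p%d", 1:6),
    sequence = replicate(6, random_seq(40)),
    bin_id = rep(c("binA", "binB", "binC"), each = 2)
  )
  bin_table <- tibble::tibble(
    bin_id = c("binA", "binB", "binC"),
    species_group_id = c("sg1", "sg2", "sg3"),
    completeness = c(80, 60, 40), contamination = c(2, 4, 3)
  )
  unbinned <- tibble::tibble(accession = "u1", sequence = random_seq(40))
  host <- tibble::tibble(accession = "h1", sequence = random_seq(50))
  db <- build_database(proteins, bin_table, unbinned = unbinned, host = host)

  # every record has exactly one code and counts per code sum to the total
  expect_false(anyNA(db$taxon_code))
  expect_equal(sum(table(db$taxon_code)), nrow(db))
  expect_setequal(unique(db$taxon_code), c("sg1", "sg2", "LOWQ", "UNBINNED", "HOST"))

  f <- tempfile(fileext = ".fasta")
  write_database_fasta(db, f)
  expect_equal(read_database_fasta(f), db)
})
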