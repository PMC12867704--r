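# Alignment, site mapping and genotype survey.

params <- alignment_params()

test_that("self-alignment is gapless with 100% identity and K/R genotype", {
  ref <- hs_sac_reference()
  twin <- protein_record("twin", ref$residues)
  aln <- align_global(ref, twin, params)
  expect_false(grepl("-", aln$aligned_a, fixed = TRUE))
  expect_false(grepl("-", aln$aligned_b, fixed = TRUE))
  expect_equal(percent_identity(aln), 100)
  gt <- call_genotype(twin, aln)
  expect_equal(gt$label, "K/R")
  expect_equal(gt$charge_class, "both-positive")
  mot <- check_motifs(twin, aln)
  expect_true(all(mot$match))
  expect_equal(mot$observed, c("AGD", "FDKG"))
})

test_that("toy alignments match manual dynamic-programming expectations", {
  aln <- align_global(protein_record("r", "KAGDR"),
                      protein_record("q", "KGDR"), params)
  expect_equal(aln$score,
               oracle_align_score("KAGDR", "KGDR", params$matrix,
                                  params$gap_open, params$gap_extend))
  expect_identical(map_site(aln, 2L), NA_integer_)  # A deleted
  expect_equal(map_site(aln, 5L), 4L)
  expect_error(map_site(aln, 6L), "out of range")

  # forced ungapped case: no identities, 4 aligned columns
  aln2 <- align_global(protein_record("r", "AAAA"),
                       protein_record("q", "GGGG"), params)
  expect_equal(nchar(aln2$aligned_a), 4L)
  expect_equal(percent_identity(aln2), 0)

  expect_equal(percent_identity(
    align_global(protein_record("r", "KAGDR"),
                 protein_record("q", "KAGDN"), params)), 80)
})

test_that("aligner is optimal versus exhaustive enumeration (len <= 6)", {
  set.seed(101)
  alphabet <- c("A", "G", "D", "R")
  for (rep in 1:40) {
    a <- paste(sample(alphabet, sample(2:6, 1), TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(2:6, 1), TRUE), collapse = "")
    aln <- align_global(protein_record("a", a), protein_record("b", b),
                        params)
    expect_equal(aln$score,
                 oracle_align_score(a, b, params$matrix, params$gap_open,
                                    params$gap_extend),
                 info = paste(a, b))
    # re-scoring the emitted alignment reproduces the reported score
    expect_equal(sacph:::rescore_alignment(aln), aln$score,
                 info = paste(a, b))
  }
})

test_that("site mapping is order-preserving and X is never an identity", {
  set.seed(202)
  for (rep in 1:20) {
    a <- paste(sample(c("A", "G", "D", "R", "K"), 12, TRUE), collapse = "")
    b <- paste(sample(c("A", "G", "D", "R", "K"), 10, TRUE), collapse = "")
    aln <- align_global(protein_record("a", a), protein_record("b", b),
                        params)
    mapped <- aln$a_to_b[!is.na(aln$a_to_b)]
    expect_true(all(diff(mapped) > 0))
  }
  alnx <- align_global(protein_record("a", "XXXX"),
                       protein_record("b", "XXXX"), params)
  expect_equal(percent_identity(alnx), 0)
})

test_that("planted genotypes are recovered from synthetic orthologs", {
  ref <- hs_sac_reference()
  for (lab in c("K/N", "N/R", "K/K")) {
    pre <- fixture_preset("mammal_kr")
    pre$n <- 5L; pre$label <- lab; pre$group <- "toy"
    gen <- gen_sequences(pre, ref, seed = 300 + nchar(lab))
    expect_true(all(gen$truth$label == lab))
    for (rec in gen$records) {
      aln <- align_global(ref, rec, params)
      expect_equal(call_genotype(rec, aln)$label, lab)
    }
  }
  # K/K carries two positive charges (the conserved insect genotype)
  pre <- fixture_preset("mammal_kr"); pre$n <- 1L; pre$label <- "K/K"
  gen <- gen_sequences(pre, ref, seed = 9)
  aln <- align_global(ref, gen$records[[1]], params)
  expect_equal(call_genotype(gen$records[[1]], aln)$charge_class,
               "both-positive")
})

test_that("motif check reports planted loop mutations", {
  ref <- hs_sac_reference()
  letters <- strsplit(ref$residues, "")[[1]]
  letters[99] <- "E"  # AGD -> AGE
  mut <- protein_record("mut", paste(letters, collapse = ""))
  aln <- align_global(ref, mut, params)
  mot <- check_motifs(mut, aln)
  expect_false(mot$match[mot$loop == "C1_b23"])
  expect_equal(mot$observed[mot$loop == "C1_b23"], "AGE")
  expect_true(mot$match[mot$loop == "C2_b23"])
})

test_that("survey aggregates recompute from rows and planted fractions", {
  ref <- hs_sac_reference()
  gen <- gen_sequences(fixture_preset("mammal_kr"), ref, seed = 42)
  sv <- survey(gen$records, ref)
  expect_equal(nrow(sv$rows), 100L)
  # recovery of the planted K/R genotype at the default indel density
  expect_gte(sv$by_group$frac_kr[sv$by_group$group == "mammal"], 0.95)
  # aggregates equal recomputation from rows
  g <- sv$rows[sv$rows$group == "mammal" & sv$rows$has_sac, ]
  expect_equal(sv$by_group$n_kr, sum(g$genotype == "K/R"))
  expect_true(all(sv$by_group$frac_kr >= 0 & sv$by_group$frac_kr <= 1))

  # zero indels: recovery is exact
  pre <- fixture_preset("mammal_kr"); pre$n <- 20L; pre$indel_rate <- 0
  gen0 <- gen_sequences(pre, ref, seed = 5)
  sv0 <- survey(gen0$records, ref)
  expect_equal(sv0$by_group$frac_kr, 1)

  # presence-only rows: 11 of 13 species with a sAC gene
  pre2 <- fixture_preset("mammal_kr"); pre2$n <- 11L
  pre2$group <- "cartilaginous_fish"; pre2$label <- "N/R"
  gen2 <- gen_sequences(pre2, ref, seed = 6)
  sv2 <- survey(gen2$records, ref,
                absent = data.frame(species = c("sp_a", "sp_b"),
                                    group = "cartilaginous_fish"))
  expect_equal(sv2$by_group$n_species, 13L)
  expect_equal(sv2$by_group$frac_has_sac, 11 / 13, tolerance = 1e-12)

  expect_error(survey(gen$records[c(1, 1)], ref), "duplicate")
  empty <- survey(list(), ref)
  expect_equal(nrow(empty$rows), 0L)
  expect_equal(nrow(empty$by_group), 0L)
})

test_that("tree annotation matches leaves and round-trips through files", {
  ref <- hs_sac_reference()
  pre <- fixture_preset("mammal_kr"); pre$n <- 3L
  gen <- gen_sequences(pre, ref, seed = 77)
  sv <- survey(gen$records, ref)
  sp <- sv$rows$species
  tr <- ape::read.tree(text = sprintf("((%s,%s),%s);",
                                      gsub(" ", "_", sp[1]),
                                      gsub(" ", "_", sp[2]),
                                      "unknown_leaf"))
  mapping <- setNames(sp[1:2], gsub(" ", "_", sp[1:2]))
  ann <- annotate_tree(tr, sv, mapping)
  expect_equal(sum(!is.na(ann$tips$genotype)), 2L)
  expect_equal(ann$unmatched, "unknown_leaf")

  tf <- tempfile(fileext = ".nwk"); af <- tempfile(fileext = ".tsv")
  write_annotated_tree(ann, tf, af)
  back <- read_annotated_tree(tf, af)
  expect_equal(back$tips$genotype, ann$tips$genotype)
  expect_equal(back$tree$tip.label, ann$tree$tip.label)
})

test_that("FASTA io round-trips records with species and group", {
  ref <- hs_sac_reference()
  pre <- fixture_preset("mammal_kr"); pre$n <- 2L
  gen <- gen_sequences(pre, ref, seed = 8)
  path <- tempfile(fileext = ".fasta")
  write_protein_fasta(gen$records, path)
  back <- read_protein_fasta(path)
  expect_equal(vapply(back, `[[`, "", "residues"),
               vapply(gen$records, `[[`, "", "residues"))
  expect_equal(vapply(back, `[[`, "", "group"),
               vapply(gen$records, `[[`, "", "group"))
})

test_that("invalid inputs are rejected", {
  expect_error(protein_record("x", ""), "non-empty")
  expect_error(protein_record("x", "KAB1"), "invalid residue")
  expect_error(alignment_params(gap_open = -1, gap_extend = -11))
  expect_error(alignment_params(substitution_matrix = "NOSUCH"),
               "unknown substitution matrix")
})
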