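# Reference-anchored ortholog genotyping of the sAC bicarbonate site.
#
# Human sAC binds bicarbonate through two positively charged residues, K95 and
# R176. Nonmammalian orthologs carry substitutions at the homologous positions
# (written "X/Y", e.g. sea urchin K/N, salmon N/R); this module aligns ortholog
# proteins to a human-numbered reference, maps reference positions through the
# alignment, and classifies the genotype and the conserved catalytic-loop
# motifs (AGD, FDKG).

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Create a protein record
#'
#' A protein record is a plain container for one amino-acid sequence with its
#' identifier, species and free-text clade label. Positions are 1-based.
#'
#' @param id Sequence identifier (e.g. an accession).
#' @param residues Uppercase amino-acid string; the 20 standard letters plus
#'   `"X"` (unknown residue) are allowed.
#' @param species Species name.
#' @param group Free-text clade label (e.g. `"mammal"`, `"echinoderm"`).
#' @return An object of class `protein_record`.
#' @export
#' @examples
#' protein_record("toy1", "KAGDR", species = "toy", group = "demo")
protein_record <- function(id, residues, species = NA_character_,
                           group = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (length(residues) != 1L || !nzchar(residues))
    stop("residues must be a non-empty string", call. = FALSE)
  letters <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(letters), AA_ALPHABET)
  if (length(bad))
    stop("invalid residue letters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(id = id, species = species, group = group,
                 residues = residues),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%s, %s), %d aa\n", x$id,
              x$species, x$group, nchar(x$residues)))
  invisible(x)
}

#' Alignment parameters
#'
#' Scoring scheme for global pairwise protein alignment with affine gaps.
#' A gap run of length L scores `gap_open + (L - 1) * gap_extend`; terminal
#' gaps are penalized like internal ones.
#'
#' @param substitution_matrix Name of a standard substitution matrix shipped
#'   with Biostrings (e.g. `"BLOSUM62"`, `"PAM250"`).
#' @param gap_open Score of the first column of a gap run (negative).
#' @param gap_extend Score of each further gap column (negative),
#'   `gap_open <= gap_extend < 0`.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = -11, gap_extend = -1) {
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stop("require gap_open <= gap_extend < 0", call. = FALSE)
  mat <- tryCatch(
    get(suppressWarnings(data(list = substitution_matrix,
                              package = "Biostrings",
                              envir = environment()))),
    error = function(e) stop("unknown substitution matrix: ",
                             substitution_matrix, call. = FALSE))
  mat <- mat[AA_ALPHABET[AA_ALPHABET %in% rownames(mat)],
             AA_ALPHABET[AA_ALPHABET %in% colnames(mat)], drop = FALSE]
  if (!all(AA_ALPHABET %in% rownames(mat)))
    stop("matrix ", substitution_matrix, " lacks amino-acid letters",
         call. = FALSE)
  mat <- mat[AA_ALPHABET, AA_ALPHABET]
  # unknown residues are scored neutrally and never count as identities
  mat["X", ] <- 0
  mat[, "X"] <- 0
  structure(list(substitution_matrix = substitution_matrix,
                 matrix = mat, gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

encode_aa <- function(residues) {
  match(strsplit(residues, "")[[1]], AA_ALPHABET)
}

#' Global pairwise protein alignment (affine gaps)
#'
#' Optimal global alignment of two protein records by the
#' Needleman-Wunsch-Gotoh dynamic program, with a deterministic traceback
#' (diagonal preferred, then gap in `b`, then gap in `a`).
#'
#' @param a,b [protein_record()] objects (`a` is treated as the reference
#'   when the alignment is used for site mapping).
#' @param params [alignment_params()].
#' @return An object of class `pairwise_alignment` with elements `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score`, and `a_to_b`, an
#'   integer vector mapping each 1-based position of `a` to its aligned
#'   position in `b` (`NA` where `a` sits opposite a gap).
#' @export
#' @examples
#' p <- alignment_params()
#' aln <- align_global(protein_record("r", "KAGDR"),
#'                     protein_record("q", "KGDR"), p)
#' aln$aligned_a
align_global <- function(a, b, params = alignment_params()) {
  stopifnot(inherits(a, "protein_record"), inherits(b, "protein_record"),
            inherits(params, "alignment_params"))
  ea <- encode_aa(a$residues)
  eb <- encode_aa(b$residues)
  res <- .gotoh_align(ea, eb, params$matrix, params$gap_open,
                      params$gap_extend)
  la <- strsplit(a$residues, "")[[1]]
  lb <- strsplit(b$residues, "")[[1]]
  ops <- res$ops
  ca <- character(length(ops)); cb <- character(length(ops))
  a_to_b <- rep(NA_integer_, length(la))
  i <- 0L; j <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op == 0L) {            # aligned column
      i <- i + 1L; j <- j + 1L
      ca[k] <- la[i]; cb[k] <- lb[j]
      a_to_b[i] <- j
    } else if (op == 1L) {     # gap in b
      i <- i + 1L
      ca[k] <- la[i]; cb[k] <- "-"
    } else {                   # gap in a
      j <- j + 1L
      ca[k] <- "-"; cb[k] <- lb[j]
    }
  }
  structure(list(id_a = a$id, id_b = b$id,
                 aligned_a = paste(ca, collapse = ""),
                 aligned_b = paste(cb, collapse = ""),
                 score = res$score, a_to_b = a_to_b, params = params),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s, score %.1f, %d columns\n",
              x$id_a, x$id_b, x$score, nchar(x$aligned_a)))
  invisible(x)
}

# Re-score a gapped alignment under its own parameters (used as an invariant).
rescore_alignment <- function(aln) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  p <- aln$params
  s <- 0
  in_gap <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-" || cb[k] == "-") {
      s <- s + if (in_gap) p$gap_extend else p$gap_open
      in_gap <- TRUE
    } else {
      s <- s + p$matrix[ca[k], cb[k]]
      in_gap <- FALSE
    }
  }
  s
}

#' Percent identity of a pairwise alignment
#'
#' @param aln A [align_global()] result.
#' @param denominator Counting policy: `"core"` (default; aligned columns
#'   excluding terminal gap runs), `"columns"` (all alignment columns),
#'   `"shorter"` (length of the shorter sequence).
#' @return Percent identity in `[0, 100]`. `"X"` never counts as an identity.
#' @export
percent_identity <- function(aln,
                             denominator = c("core", "columns", "shorter")) {
  denominator <- match.arg(denominator)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  core <- if (any(both)) seq(min(which(both)), max(which(both)))
          else integer(0)
  ident <- ca == cb & both & ca != "X"
  den <- switch(denominator,
                core = length(core),
                columns = length(ca),
                shorter = min(sum(ca != "-"), sum(cb != "-")))
  if (den == 0) stop("zero-length denominator", call. = FALSE)
  num <- switch(denominator,
                core = sum(ident[core]),
                sum(ident))
  100 * num / den
}

#' Map a reference position through an alignment
#'
#' @param aln Alignment whose `a` sequence is the reference.
#' @param ref_pos 1-based position in the reference.
#' @return The aligned 1-based query position, or `NA_integer_` if the
#'   reference position sits opposite a gap.
#' @export
map_site <- function(aln, ref_pos) {
  n <- length(aln$a_to_b)
  if (!is.numeric(ref_pos) || any(ref_pos < 1) || any(ref_pos > n))
    stop("ref_pos out of range 1..", n, call. = FALSE)
  aln$a_to_b[as.integer(ref_pos)]
}

#' Reference site map for the bicarbonate-binding and catalytic residues
#'
#' Named reference positions (human sAC numbering) of the two
#' bicarbonate-coordinating residues, the catalytic residues, and the two
#' beta2/3 loops with their expected motifs.
#'
#' @param reference_id Identifier of the reference sequence the positions
#'   refer to.
#' @return An object of class `site_map`.
#' @export
hs_sac_sites <- function(reference_id = "HsSAC_t_synthetic") {
  structure(list(
    reference_id = reference_id,
    bicarbonate = c(K95 = 95L, R176 = 176L),
    catalytic = c(D47 = 47L, D99 = 99L, K144 = 144L, K334 = 334L,
                  N412 = 412L, R416 = 416L),
    loops = list(
      C1_b23 = list(range = c(97L, 99L), motif = "AGD"),
      C2_b23 = list(range = c(338L, 341L), motif = "FDKG"))),
    class = "site_map")
}

POSITIVE_AA <- c("K", "R", "H")

#' Call the bicarbonate-site genotype of a query protein
#'
#' Reads the residues at the query positions homologous to K95 and R176 of
#' the human reference and builds the "X/Y" genotype label. Positions lost to
#' gaps are written `"-"` and treated as non-positive.
#'
#' @param query The query [protein_record()].
#' @param aln Alignment of the reference (`a`) against `query` (`b`).
#' @param sites A [hs_sac_sites()] site map for the same reference.
#' @return A list of class `genotype_call` with `residue_at_k95`,
#'   `residue_at_r176`, `label` and `charge_class` (one of `"both-positive"`,
#'   `"one-positive"`, `"none-positive"`).
#' @export
call_genotype <- function(query, aln, sites = hs_sac_sites()) {
  if (!identical(aln$id_a, sites$reference_id))
    stop("alignment reference '", aln$id_a, "' does not match site map '",
         sites$reference_id, "'", call. = FALSE)
  lq <- strsplit(query$residues, "")[[1]]
  res_at <- function(ref_pos) {
    qp <- map_site(aln, ref_pos)
    if (is.na(qp)) "-" else lq[qp]
  }
  r95 <- res_at(sites$bicarbonate[["K95"]])
  r176 <- res_at(sites$bicarbonate[["R176"]])
  npos <- sum(c(r95, r176) %in% POSITIVE_AA)
  structure(list(
    residue_at_k95 = r95, residue_at_r176 = r176,
    label = paste(r95, r176, sep = "/"),
    charge_class = c("none-positive", "one-positive",
                     "both-positive")[npos + 1L]),
    class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> %s (%s)\n", x$label, x$charge_class))
  invisible(x)
}

#' Check the conserved catalytic-loop motifs in a query protein
#'
#' For each loop in the site map, maps the reference loop range through the
#' alignment and compares the query substring against the expected motif.
#'
#' @inheritParams call_genotype
#' @return A data frame with one row per loop: `loop`, `expected`,
#'   `observed` (`NA` if any loop position is unmapped), `query_start`,
#'   `query_end`, `match`.
#' @export
check_motifs <- function(query, aln, sites = hs_sac_sites()) {
  lq <- strsplit(query$residues, "")[[1]]
  rows <- lapply(names(sites$loops), function(nm) {
    loop <- sites$loops[[nm]]
    qp <- map_site(aln, seq(loop$range[1], loop$range[2]))
    if (anyNA(qp)) {
      data.frame(loop = nm, expected = loop$motif, observed = NA_character_,
                 query_start = NA_integer_, query_end = NA_integer_,
                 match = FALSE)
    } else {
      obs <- paste(lq[qp], collapse = "")
      data.frame(loop = nm, expected = loop$motif, observed = obs,
                 query_start = qp[1], query_end = qp[length(qp)],
                 match = identical(obs, loop$motif))
    }
  })
  do.call(rbind, rows)
}

#' Survey the bicarbonate-site genotype across a set of orthologs
#'
#' Aligns every record to the reference, calls the genotype and the loop
#' motifs, and aggregates per clade group. Species known to lack a sAC gene
#' can be supplied as presence-only rows via `absent`.
#'
#' @param records List of [protein_record()] queries (unique ids).
#' @param reference The reference [protein_record()].
#' @param sites [hs_sac_sites()] map for the reference.
#' @param params [alignment_params()].
#' @param absent Optional data frame with columns `species` and `group`,
#'   listing species whose genome lacks a sAC gene; they enter the survey
#'   with `has_sac = FALSE` and no genotype.
#' @return A list of class `survey_table` with `rows` (one row per species)
#'   and `by_group` (per-group counts and fractions).
#' @export
survey <- function(records, reference, sites = hs_sac_sites(),
                   params = alignment_params(), absent = NULL) {
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate record ids", call. = FALSE)
  if (reference$id %in% ids)
    stop("reference must be distinct from the queries", call. = FALSE)
  rows <- lapply(records, function(rec) {
    aln <- align_global(reference, rec, params)
    gt <- call_genotype(rec, aln, sites)
    mot <- check_motifs(rec, aln, sites)
    data.frame(id = rec$id, species = rec$species, group = rec$group,
               has_sac = TRUE, genotype = gt$label,
               charge_class = gt$charge_class,
               agd_match = mot$match[mot$loop == "C1_b23"],
               fdkg_match = mot$match[mot$loop == "C2_b23"],
               identity = percent_identity(aln))
  })
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), species = character(0),
               group = character(0), has_sac = logical(0),
               genotype = character(0), charge_class = character(0),
               agd_match = logical(0), fdkg_match = logical(0),
               identity = numeric(0))
  if (!is.null(absent) && nrow(absent)) {
    rows <- rbind(rows, data.frame(
      id = NA_character_, species = absent$species, group = absent$group,
      has_sac = FALSE, genotype = NA_character_,
      charge_class = NA_character_, agd_match = NA, fdkg_match = NA,
      identity = NA_real_))
  }
  by_group <- if (nrow(rows)) {
    agg <- lapply(split(rows, rows$group), function(g) {
      present <- g[g$has_sac, , drop = FALSE]
      data.frame(group = g$group[1], n_species = nrow(g),
                 n_has_sac = nrow(present),
                 frac_has_sac = nrow(present) / nrow(g),
                 n_kr = sum(present$genotype == "K/R"),
                 frac_kr = if (nrow(present))
                   sum(present$genotype == "K/R") / nrow(present)
                 else NA_real_)
    })
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    out
  } else {
    data.frame(group = character(0), n_species = integer(0),
               n_has_sac = integer(0), frac_has_sac = numeric(0),
               n_kr = integer(0), frac_kr = numeric(0))
  }
  structure(list(rows = rows, by_group = by_group), class = "survey_table")
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("<survey_table> %d species, %d groups\n", nrow(x$rows),
              nrow(x$by_group)))
  print(x$by_group)
  invisible(x)
}

#' Annotate a phylogenetic tree with survey results
#'
#' Attaches presence/genotype attributes from a [survey()] table to the
#' matching leaves of a tree read with ape. The tree is an input (e.g. a
#' published time-calibrated tree); no tree inference is done here.
#'
#' @param tree An `ape::phylo` object or path to a newick file.
#' @param table A [survey()] result.
#' @param mapping Optional named character vector translating leaf labels to
#'   table species names.
#' @return A list of class `annotated_tree` with the `tree`, a `tips` data
#'   frame (leaf, species, has_sac, genotype) and the `unmatched` leaf labels.
#' @export
annotate_tree <- function(tree, table, mapping = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed newick tree", call. = FALSE)
  leaves <- tree$tip.label
  species <- if (is.null(mapping)) leaves else {
    out <- unname(mapping[leaves])
    ifelse(is.na(out), leaves, out)
  }
  idx <- match(species, table$rows$species)
  tips <- data.frame(leaf = leaves, species = species,
                     has_sac = table$rows$has_sac[idx],
                     genotype = table$rows$genotype[idx])
  structure(list(tree = tree, tips = tips,
                 unmatched = leaves[is.na(idx)]),
            class = "annotated_tree")
}

#' Write / read an annotated tree
#'
#' Serializes the tree as newick and the leaf annotations as TSV so the
#' annotation round-trips losslessly through plain-text files.
#'
#' @param x An [annotate_tree()] result.
#' @param tree_file,annotation_file Output paths.
#' @return `write_annotated_tree` returns the paths invisibly;
#'   `read_annotated_tree` returns an `annotated_tree`.
#' @export
write_annotated_tree <- function(x, tree_file, annotation_file) {
  ape::write.tree(x$tree, file = tree_file)
  write.table(x$tips, annotation_file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(tree = tree_file, annotations = annotation_file))
}

#' @rdname write_annotated_tree
#' @export
read_annotated_tree <- function(tree_file, annotation_file) {
  tree <- ape::read.tree(tree_file)
  tips <- read.delim(annotation_file, stringsAsFactors = FALSE)
  tips$has_sac <- as.logical(tips$has_sac)
  structure(list(tree = tree, tips = tips,
                 unmatched = tips$leaf[is.na(tips$genotype) & !tips$has_sac]),
            class = "annotated_tree")
}

#' Read protein records from a FASTA file
#'
#' Description lines of the form `id species=... group=...` are parsed into
#' the record fields.
#'
#' @param path FASTA file path.
#' @return A list of [protein_record()] objects.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  lapply(seq_along(set), function(i) {
    desc <- names(set)[i]
    toks <- strsplit(desc, "\\s+")[[1]]
    id <- toks[1]
    kv <- grep("=", toks[-1], value = TRUE)
    vals <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    protein_record(id, as.character(set[[i]]),
                   species = gsub("_", " ", vals["species"] %||% NA),
                   group = unname(vals["group"]) %||% NA)
  })
}

#' Write protein records to a FASTA file
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(
    vapply(records, function(r) r$residues, character(1)))
  names(seqs) <- vapply(records, function(r) {
    paste0(r$id,
           if (!is.na(r$species))
             paste0(" species=", gsub(" ", "_", r$species)) else "",
           if (!is.na(r$group)) paste0(" group=", r$group) else "")
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' The packaged human sAC reference (synthetic stand-in)
#'
#' Loads the reference protein shipped with the package. It is a synthetic
#' stand-in for the human sAC catalytic region: the bicarbonate-coordinating
#' residues (K95, R176), the catalytic residues and the two beta2/3 loop
#' motifs (AGD at 97-99, FDKG at 338-341) are planted at the human
#' coordinates used throughout, while the remaining positions are arbitrary.
#' Mapping and genotyping results against this reference therefore use the
#' human numbering, but the sequence itself is not the natural human protein.
#'
#' @return A [protein_record()].
#' @export
hs_sac_reference <- function() {
  path <- system.file("extdata", "hs_sac_synthetic.fasta", package = "sacph")
  read_protein_fasta(path)[[1]]
}
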