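# Synthetic-data generators. Every generator is deterministic given its
# seed and records the planted truth needed to verify downstream stages
# without re-alignment.

codon_table <- function() {
  if (is.null(the$codons_by_aa)) {
    gc <- Biostrings::GENETIC_CODE
    the$codons_by_aa <- split(names(gc), unname(gc))
  }
  the$codons_by_aa
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

codon_for <- function(aa) sample1(codon_table()[[aa]])

#' Per-site substitution spectrum for homolog simulation
#'
#' At each codon site of a simulated homolog pair the amino acid is kept
#' with probability `p_identical`, replaced by a conservative partner
#' (BLOSUM62 score > 0 against the original) with `p_conservative`, and by
#' a radical partner (score <= 0) with `p_radical`. Whole-codon indels
#' occur at `indel_rate` per site, keeping frames intact.
#'
#' @param p_identical,p_conservative,p_radical Site-class probabilities;
#'   must be non-negative and sum to 1 (within 1e-12).
#' @param indel_rate Per-site probability of a codon insertion/deletion.
#' @param length_codons Gene length in codons (>= 30).
#' @return A list of class `substitution_spectrum` carrying
#'   `expected_ratio = p_identical / (p_identical + p_conservative)`.
#' @export
substitution_spectrum <- function(p_identical, p_conservative, p_radical,
                                  indel_rate = 0, length_codons = 300L) {
  p <- c(p_identical, p_conservative, p_radical)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    abort("site-class probabilities must be non-negative and sum to 1")
  }
  if (length_codons < 30) abort("length_codons must be at least 30")
  structure(
    list(
      p_identical = p_identical, p_conservative = p_conservative,
      p_radical = p_radical, indel_rate = indel_rate,
      length_codons = as.integer(length_codons),
      expected_ratio = if (p_identical + p_conservative > 0) {
        p_identical / (p_identical + p_conservative)
      } else {
        NA_real_
      }
    ),
    class = "substitution_spectrum"
  )
}

# ancestral residues are drawn from the 17 residues that have at least one
# conservative BLOSUM62 partner; C, G and P have none, so a conservative
# event on them would be unsatisfiable
ancestral_alphabet <- function() {
  cp <- conservative_partners()
  names(cp)[lengths(cp) > 0]
}

substitute_residue <- function(aa, class) {
  if (class == "identical") return(aa)
  pool <- if (class == "conservative") {
    conservative_partners()[[aa]]
  } else {
    radical_partners()[[aa]]
  }
  if (!length(pool)) {
    abort(sprintf("residue '%s' has no %s partner in BLOSUM62", aa, class))
  }
  sample1(pool)
}

#' Simulate one homologous coding-sequence pair
#'
#' Builds an ancestral in-frame coding sequence and a diverged copy whose
#' per-site behaviour follows `spectrum`. Synonymous codons are chosen
#' uniformly on both sides, so nucleotide identity is low even at identical
#' amino-acid sites. Neither sequence contains an internal stop codon.
#'
#' @param spectrum A [substitution_spectrum()].
#' @param seed Integer seed; output is deterministic given it.
#' @param id Base identifier for the pair.
#' @return A list with `query` and `subject` records (`id`, `seq`),
#'   `expected_ratio`, and `site_log` — a tibble of per-site ancestral and
#'   derived residues with the drawn class (`identical`, `conservative`,
#'   `radical`, `insertion`, `deletion`), sufficient to compute every
#'   expected statistic without re-alignment.
#' @export
simulate_homolog_pair <- function(spectrum, seed, id = "pair") {
  stopifnot(inherits(spectrum, "substitution_spectrum"))
  set.seed(seed)
  n <- spectrum$length_codons
  anc <- sample(ancestral_alphabet(), n, replace = TRUE)
  cls <- sample(
    c("identical", "conservative", "radical"), n, replace = TRUE,
    prob = c(spectrum$p_identical, spectrum$p_conservative, spectrum$p_radical)
  )
  der <- vapply(seq_len(n), function(k) substitute_residue(anc[k], cls[k]), "")
  site_log <- tibble(site = seq_len(n), anc_aa = anc, der_aa = der, class = cls)
  if (spectrum$indel_rate > 0) {
    indel <- runif(n) < spectrum$indel_rate
    kind <- ifelse(indel, sample(c("insertion", "deletion"), n, replace = TRUE),
                   NA_character_)
    rows <- purrr::map_dfr(seq_len(n), function(k) {
      base <- site_log[k, ]
      if (!indel[k]) return(base)
      if (kind[k] == "deletion") {
        base$der_aa <- NA_character_
        base$class <- "deletion"
        return(base)
      }
      ins <- tibble(site = k, anc_aa = NA_character_,
                    der_aa = sample1(ancestral_alphabet()),
                    class = "insertion")
      bind_rows(base, ins)
    })
    site_log <- rows
  }
  q_aa <- site_log$anc_aa[!is.na(site_log$anc_aa)]
  s_aa <- site_log$der_aa[!is.na(site_log$der_aa)]
  qseq <- paste(vapply(q_aa, codon_for, ""), collapse = "")
  sseq <- paste(vapply(s_aa, codon_for, ""), collapse = "")
  list(
    query = list(id = paste0(id, "_q"), seq = qseq),
    subject = list(id = paste0(id, "_s"), seq = sseq),
    expected_ratio = spectrum$expected_ratio,
    site_log = site_log
  )
}

#' Simulate a multi-function homolog panel with planted enrichment
#'
#' Draws `n_genes_per_function` homolog pairs for each named function from
#' that function's substitution spectrum, so the contrast between high-
#' and low-substitution functional classes is known by construction.
#'
#' @param n_genes_per_function Genes per function.
#' @param spectra_by_function Named list (>= 2 entries) of
#'   [substitution_spectrum()] objects.
#' @param seed Integer seed.
#' @param categories Optional named character vector mapping function name
#'   to a broader category; defaults to the function's own name.
#' @return A list with `query_set` and `subject_set` sequence tibbles, an
#'   `annotation` tibble (`gene_id`, `fun`, `category`, `evalue`), and
#'   `truth` (`gene_id`, `fun`, `category`, `expected_ratio`).
#' @export
simulate_function_panel <- function(n_genes_per_function, spectra_by_function,
                                    seed, categories = NULL) {
  if (length(spectra_by_function) < 2) {
    abort("at least 2 functions with distinct spectra are required")
  }
  funs <- names(spectra_by_function)
  if (is.null(categories)) categories <- setNames(funs, funs)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          length(funs) * n_genes_per_function)
  idx <- 0L
  out <- purrr::map_dfr(seq_along(funs), function(fi) {
    purrr::map_dfr(seq_len(n_genes_per_function), function(gi) {
      idx <<- idx + 1L
      gene <- sprintf("g%02d_%03d", fi, gi)
      pair <- simulate_homolog_pair(spectra_by_function[[fi]],
                                    seed = sub_seeds[idx], id = gene)
      tibble(
        gene_id = gene, fun = funs[fi],
        category = unname(categories[funs[fi]]),
        expected_ratio = pair$expected_ratio,
        q_id = pair$query$id, q_seq = pair$query$seq,
        s_id = pair$subject$id, s_seq = pair$subject$seq
      )
    })
  })
  list(
    query_set = tibble(id = out$q_id, seq = out$q_seq, description = out$gene_id),
    subject_set = tibble(id = out$s_id, seq = out$s_seq, description = out$gene_id),
    annotation = tibble(gene_id = out$q_id, fun = out$fun,
                        category = out$category, evalue = 1e-50),
    truth = tibble(gene_id = out$q_id, fun = out$fun, category = out$category,
                   expected_ratio = out$expected_ratio)
  )
}

# derive a spectrum-controlled homolog of an existing in-frame coding
# sequence; asserts when a conservative event lands on a partnerless residue
mutate_coding_seq <- function(seq, spectrum) {
  aa <- strsplit(as.character(Biostrings::translate(Biostrings::DNAString(seq))),
                 "")[[1]]
  if (any(aa == "*")) abort("coding sequence contains a stop codon")
  cls <- sample(
    c("identical", "conservative", "radical"), length(aa), replace = TRUE,
    prob = c(spectrum$p_identical, spectrum$p_conservative, spectrum$p_radical)
  )
  der <- vapply(seq_along(aa), function(k) substitute_residue(aa[k], cls[k]), "")
  paste(vapply(der, codon_for, ""), collapse = "")
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

random_coding_seq <- function(n_codons) {
  aa <- sample(STANDARD_AA, n_codons, replace = TRUE)
  paste(vapply(aa, codon_for, ""), collapse = "")
}

#' Simulate target datasets with a planted presence/absence plan
#'
#' For each dataset, genes marked present appear as spectrum-controlled
#' mutated homologs; absent genes are left out entirely; unrelated random
#' coding sequences are added as decoys. Datasets named in `genome_like`
#' emulate genomic super contigs: each homolog is split into two exon-like
#' fragments joined by a random spacer, so only local segments align.
#'
#' @param gene_set Tibble of coding sequences (`id`, `seq`), e.g. the query
#'   side of [simulate_function_panel()].
#' @param presence_plan Tibble (`gene_id`, `dataset`, `present`).
#' @param decoy_count Decoys per dataset.
#' @param seed Integer seed.
#' @param spectrum Spectrum used to derive homologs (defaults to a mild
#'   0.9/0.05/0.05 regime).
#' @param genome_like Character vector of dataset names to fragment.
#' @param spacer_nt Range of random-spacer lengths for genome-like targets.
#' @return A list with `datasets` (named list of sequence tibbles) and
#'   `truth` (the presence plan).
#' @export
simulate_target_datasets <- function(gene_set, presence_plan, decoy_count = 0L,
                                     seed = 1L,
                                     spectrum = substitution_spectrum(0.9, 0.05, 0.05),
                                     genome_like = character(),
                                     spacer_nt = c(60L, 150L)) {
  unknown <- setdiff(presence_plan$gene_id, gene_set$id)
  if (length(unknown)) {
    abort(paste0("presence_plan references unknown gene(s): ",
                 paste(unknown, collapse = ", ")))
  }
  set.seed(seed)
  datasets <- lapply(setNames(nm = unique(presence_plan$dataset)), function(ds) {
    plan <- presence_plan[presence_plan$dataset == ds & presence_plan$present, ]
    homs <- purrr::map_dfr(plan$gene_id, function(g) {
      seq <- mutate_coding_seq(gene_set$seq[gene_set$id == g], spectrum)
      if (ds %in% genome_like) {
        n_cod <- nchar(seq) / 3
        cut <- 3L * sample(seq(10L, n_cod - 10L), 1L)
        spacer <- random_nt(sample(seq(spacer_nt[1], spacer_nt[2]), 1L))
        seq <- paste0(substr(seq, 1L, cut), spacer,
                      substr(seq, cut + 1L, nchar(seq)))
      }
      tibble(id = paste0(ds, "_", g), seq = seq, description = g)
    })
    decoys <- if (decoy_count > 0) {
      tibble(
        id = sprintf("%s_decoy_%03d", ds, seq_len(decoy_count)),
        seq = vapply(seq_len(decoy_count),
                     function(k) random_coding_seq(100L), ""),
        description = "decoy"
      )
    } else {
      tibble(id = character(), seq = character(), description = character())
    }
    bind_rows(homs, decoys)
  })
  list(datasets = datasets, truth = presence_plan)
}

#' Simulate an EST collection with known cluster structure
#'
#' Each cluster has a random exemplar sequence; its ESTs are near-identical
#' copies with at most `mutation_rate` per-base substitutions. The skewed
#' cluster-size profile of a non-normalized cDNA library is supplied
#' through `size_distribution`.
#'
#' @param n_clusters Number of clusters.
#' @param size_distribution Integer vector of cluster sizes (length
#'   `n_clusters`), or a function of `n_clusters` returning one.
#' @param seed Integer seed; output is byte-identical across runs given it.
#' @param exemplar_len_nt Exemplar length.
#' @param mutation_rate Per-base substitution probability per EST copy.
#' @return A list with `sequences` (tibble `id`, `seq`, `description`) and
#'   `truth` (tibble `est_id`, `cluster`).
#' @export
simulate_est_collection <- function(n_clusters, size_distribution, seed = 1L,
                                    exemplar_len_nt = 300L,
                                    mutation_rate = 0.01) {
  set.seed(seed)
  sizes <- if (is.function(size_distribution)) {
    size_distribution(n_clusters)
  } else {
    size_distribution
  }
  stopifnot(length(sizes) == n_clusters, all(sizes >= 1))
  bases <- c("A", "C", "G", "T")
  out <- purrr::map_dfr(seq_len(n_clusters), function(ci) {
    ex <- sample(bases, exemplar_len_nt, replace = TRUE)
    purrr::map_dfr(seq_len(sizes[ci]), function(k) {
      mut <- runif(exemplar_len_nt) < mutation_rate
      copy <- ex
      if (any(mut)) {
        copy[mut] <- vapply(copy[mut], function(b) sample1(setdiff(bases, b)), "")
      }
      tibble(cluster = ci, seq = paste(copy, collapse = ""))
    })
  })
  out$est_id <- sprintf("est_%05d", seq_len(nrow(out)))
  list(
    sequences = tibble(id = out$est_id, seq = out$seq,
                       description = sprintf("cluster_%04d", out$cluster)),
    truth = tibble(est_id = out$est_id, cluster = out$cluster)
  )
}
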