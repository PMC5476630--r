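#' Configuration of the synthetic endosperm bundle
#'
#' The generator emulates the study design this package analyses: nine
#' RNA-Seq libraries (three endosperm cell types x three stages, one
#' library each), an annotation mixing annotated coding transcripts with
#' novel assembled ones, planted co-expression structure, and every
#' confounder class the lncRNA filter chain must remove. Expression is
#' prototype x fold-pattern x lognormal noise (additive Gaussian on log10
#' FPKM), keeping FPKM non-negative.
#'
#' Novel transcripts are partitioned into a true-lncRNA fraction and four
#' single-violation confounder classes -- too short (< 200 nt), long-ORF,
#' blacklist match, annotation overlap -- plus a never-expressed remainder;
#' each confounder violates exactly one filter. Length distributions are
#' lognormal, sized so most lncRNAs fall under 1.1 kb while most coding
#' transcripts exceed it.
#'
#' @param seed Integer seed; the same seed yields a byte-identical bundle.
#' @param n_coding,n_novel Transcript counts per class.
#' @param n_clusters_planted Number of planted prototype patterns (default
#'   6: three tissue-up, two stage-up, one single tissue/stage point).
#' @param prototype_patterns Optional list of 9-vectors of relative
#'   expression multipliers overriding the defaults.
#' @param fold_strength Planted fold ratio (>= 4 so planted calls clear the
#'   4-fold threshold; default 8).
#' @param noise_sd Standard deviation of the log10-FPKM noise (default 0.3).
#' @param frac_true_lncrna,frac_short,frac_long_orf,frac_blacklist,frac_annot_overlap
#'   Proportions of the novel set (must sum to <= 1; the remainder is a
#'   never-expressed class caught by the expression filter).
#' @param frac_regulated_coding Fraction of coding transcripts assigned a
#'   planted pattern (default 2/3; the rest are flat).
#' @param frac_regulated_lnc Fraction of true lncRNAs assigned a planted
#'   pattern (default 0.85, the spatio-temporal share observed for
#'   endosperm lncRNAs).
#' @param peak_assoc_prob Probability that a regulated lncRNA locus carries
#'   an H3K27me3 peak (default 0.8).
#' @param peak_background_prob Peak probability at any other locus
#'   (default 0.1).
#' @param coding_base_fpkm,lnc_base_fpkm Baseline FPKM of the two classes.
#' @param lnc_len_meanlog,lnc_len_sdlog,coding_len_meanlog,coding_len_sdlog
#'   Lognormal length parameters; defaults put ~5% of lncRNAs and ~89% of
#'   coding transcripts above 1.1 kb.
#' @param neighbour_prob Probability a true lncRNA is placed within 10 kb
#'   of a coding gene (default 0.5); half of those copy the neighbour's
#'   expression pattern.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_coding = 600L, n_novel = 300L,
                              n_clusters_planted = 6L,
                              prototype_patterns = NULL,
                              fold_strength = 8, noise_sd = 0.3,
                              frac_true_lncrna = 0.5, frac_short = 0.1,
                              frac_long_orf = 0.1, frac_blacklist = 0.1,
                              frac_annot_overlap = 0.1,
                              frac_regulated_coding = 2 / 3,
                              frac_regulated_lnc = 0.85,
                              peak_assoc_prob = 0.8,
                              peak_background_prob = 0.1,
                              coding_base_fpkm = 20, lnc_base_fpkm = 2,
                              lnc_len_meanlog = log(500), lnc_len_sdlog = 0.5,
                              coding_len_meanlog = log(2000),
                              coding_len_sdlog = 0.5,
                              neighbour_prob = 0.5) {
  fracs <- c(frac_true_lncrna, frac_short, frac_long_orf, frac_blacklist,
             frac_annot_overlap)
  if (any(fracs < 0 | fracs > 1)) abort("novel-class proportions must be in [0, 1]")
  if (sum(fracs) > 1 + 1e-12) abort("novel-class proportions must sum to <= 1")
  if (fold_strength < 4) abort("fold_strength must be >= 4")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  cfg <- list(
    seed = as.integer(seed), n_coding = as.integer(n_coding),
    n_novel = as.integer(n_novel),
    n_clusters_planted = as.integer(n_clusters_planted),
    prototype_patterns = prototype_patterns,
    fold_strength = fold_strength, noise_sd = noise_sd,
    frac_true_lncrna = frac_true_lncrna, frac_short = frac_short,
    frac_long_orf = frac_long_orf, frac_blacklist = frac_blacklist,
    frac_annot_overlap = frac_annot_overlap,
    frac_regulated_coding = frac_regulated_coding,
    frac_regulated_lnc = frac_regulated_lnc,
    peak_assoc_prob = peak_assoc_prob,
    peak_background_prob = peak_background_prob,
    coding_base_fpkm = coding_base_fpkm, lnc_base_fpkm = lnc_base_fpkm,
    lnc_len_meanlog = lnc_len_meanlog, lnc_len_sdlog = lnc_len_sdlog,
    coding_len_meanlog = coding_len_meanlog,
    coding_len_sdlog = coding_len_sdlog,
    neighbour_prob = neighbour_prob
  )
  structure(cfg, class = "simulation_config")
}

#' Default planted expression prototypes
#'
#' Builds `k` prototype patterns as 9-vectors of multiplicative fold
#' factors over the baseline FPKM, in canonical sample order. The first six
#' are BETL-up, AL-up, SE-up, 8-DAP-up, 12-DAP-up and a BETL-at-8-DAP
#' "single point" pattern (fold factors multiply, so the point pattern is
#' both tissue- and stage-called); further patterns cycle through
#' tissue x stage points. Each pattern carries its intended regulation
#' calls, which become the truth table.
#'
#' @param k Number of patterns.
#' @param fold Fold factor.
#' @return A tibble: `cluster`, `name`, `multipliers` (list of 9-vectors),
#'   `spatial_up`, `temporal_up` (list-columns of intended calls).
#' @export
planted_patterns <- function(k = 6L, fold = 8) {
  keys <- sample_keys()
  tissue_mult <- function(t) ifelse(keys$tissue == t, fold, 1)
  stage_mult <- function(d) ifelse(keys$dap == d, fold, 1)
  base <- list(
    list(name = "BETL_up", m = tissue_mult("BETL"), sp = "BETL", tp = character()),
    list(name = "AL_up", m = tissue_mult("AL"), sp = "AL", tp = character()),
    list(name = "SE_up", m = tissue_mult("SE"), sp = "SE", tp = character()),
    list(name = "DAP8_up", m = stage_mult(8L), sp = character(), tp = "8"),
    list(name = "DAP12_up", m = stage_mult(12L), sp = character(), tp = "12"),
    list(name = "BETL08_point", m = tissue_mult("BETL") * stage_mult(8L),
         sp = "BETL", tp = "8")
  )
  if (k > length(base)) {
    extra_ix <- seq_len(k - length(base))
    combos <- expand.grid(tissue = tissue_levels(), dap = dap_levels(),
                          stringsAsFactors = FALSE)
    for (i in extra_ix) {
      cb <- combos[(i - 1) %% nrow(combos) + 1, ]
      base[[length(base) + 1]] <- list(
        name = paste0(cb$tissue, sprintf("%02d", cb$dap), "_point_", i),
        m = tissue_mult(cb$tissue) * stage_mult(cb$dap),
        sp = cb$tissue, tp = as.character(cb$dap)
      )
    }
  }
  base <- base[seq_len(k)]
  tibble::tibble(
    cluster = seq_len(k),
    name = purrr::map_chr(base, "name"),
    multipliers = purrr::map(base, "m"),
    spatial_up = purrr::map(base, "sp"),
    temporal_up = purrr::map(base, "tp")
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random sequence guaranteed to carry no complete ORF of >= max_orf codons
random_noncoding_dna <- function(n, max_orf = 100L) {
  for (i in 1:50) {
    s <- random_dna(n)
    if (longest_orf(s) < max_orf) return(s)
  }
  abort("failed to generate an ORF-free sequence")  # practically unreachable
}

# sequence of length n containing an ORF of exactly `aa` amino acids
orf_dna <- function(n, aa = 110L) {
  need <- 3 * (aa + 1)  # ATG + (aa - 1) codons + stop
  if (n < need + 6) n <- need + 6
  non_stop <- setdiff(c(outer(c(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                      paste0)), c("A", "C", "G", "T"), paste0)),
                      c("TAA", "TAG", "TGA", "ATG"))
  body <- paste(sample(non_stop, aa - 1, replace = TRUE), collapse = "")
  prefix_len <- sample.int(n - need - 3, 1) + 1
  prefix <- random_noncoding_dna(prefix_len, 100L)
  suffix <- random_noncoding_dna(n - need - prefix_len, 100L)
  paste0(prefix, "ATG", body, "TAA", suffix)
}

# split a spliced length into exon lengths and lay the exons from `start`
# with random introns; returns a 2-column matrix (0-based half-open)
make_exons <- function(start, spliced_len, n_exons) {
  n_exons <- max(1L, min(n_exons, spliced_len %/% 50))
  if (n_exons == 1) {
    return(cbind(start = start, end = start + spliced_len))
  }
  cuts <- sort(sample.int(spliced_len - 1, n_exons - 1))
  lens <- diff(c(0L, cuts, spliced_len))
  introns <- sample(100:500, n_exons - 1, replace = TRUE)
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  pos <- start
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + lens[i]
    pos <- ends[i] + if (i < n_exons) introns[i] else 0L
  }
  cbind(start = starts, end = ends)
}

#' Generate a complete synthetic input bundle
#'
#' Builds annotation, sequences, expression, H3K27me3 peaks, catalogues,
#' blacklist and truth tables with planted structure (see
#' [simulation_config()]), optionally writing all files to `dir` in the
#' plain-text formats the readers of this package consume.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory (created if needed).
#' @return A list of class `endo_bundle` with elements `transcripts`
#'   (tibble, with sequences), `expr`, `peaks`, `go_map`, `tf_ids`,
#'   `meg_ids`, `peg_ids`, `blacklist_intervals`, `blacklist_seqs`,
#'   `truth` (one row per transcript with planted class, cluster, calls,
#'   peak and neighbour fields), `patterns` and `config`. When `dir` is
#'   given, a `files` element lists the paths written.
#' @export
generate_bundle <- function(config = simulation_config(), dir = NULL) {
  bundle <- with_preserved_seed(config$seed, build_bundle(config))
  if (!is.null(dir)) {
    bundle$files <- write_bundle(bundle, dir)
  }
  bundle
}

build_bundle <- function(config) {
  patterns <- if (is.null(config$prototype_patterns)) {
    planted_patterns(config$n_clusters_planted, config$fold_strength)
  } else {
    tibble::tibble(
      cluster = seq_along(config$prototype_patterns),
      name = paste0("custom_", seq_along(config$prototype_patterns)),
      multipliers = config$prototype_patterns,
      spatial_up = list(character()),
      temporal_up = list(character())
    )
  }
  k <- nrow(patterns)
  n_chrom <- 5L
  slot_width <- 50000L

  # ---- class layout over the novel set -------------------------------
  n_novel <- config$n_novel
  n_true <- round(n_novel * config$frac_true_lncrna)
  n_short <- round(n_novel * config$frac_short)
  n_long_orf <- round(n_novel * config$frac_long_orf)
  n_black <- round(n_novel * config$frac_blacklist)
  n_overlap <- round(n_novel * config$frac_annot_overlap)
  n_low <- n_novel - n_true - n_short - n_long_orf - n_black - n_overlap
  if (n_low < 0) abort("novel-class proportions leave a negative remainder")
  classes <- c(rep("lncrna", n_true), rep("short", n_short),
               rep("long_orf", n_long_orf), rep("blacklist", n_black),
               rep("annot_overlap", n_overlap), rep("low_expression", n_low))

  # ---- coding transcripts --------------------------------------------
  n_coding <- config$n_coding
  coding_ids <- sprintf("GENE%05d", seq_len(n_coding))
  coding_len <- pmax(400L, as.integer(round(
    rlnorm(n_coding, config$coding_len_meanlog, config$coding_len_sdlog))))
  slot <- 0L
  next_slot <- function() {
    slot <<- slot + 1L
    list(chrom = paste0("chr", (slot - 1L) %% n_chrom + 1L),
         start = 10000L + ((slot - 1L) %/% n_chrom) * slot_width)
  }
  coding_rows <- vector("list", n_coding)
  for (i in seq_len(n_coding)) {
    pos <- next_slot()
    ex <- make_exons(pos$start, coding_len[i], sample(2:4, 1))
    coding_rows[[i]] <- tibble::tibble(
      transcript_id = coding_ids[i],
      gene_id = paste0(coding_ids[i], "g"),
      chrom = pos$chrom, strand = sample(c("+", "-"), 1),
      biotype = "annotated_coding",
      exons = list(ex), length = coding_len[i]
    )
  }
  coding <- purrr::list_rbind(coding_rows)
  coding$sequence <- purrr::map_chr(coding$length, function(len) {
    orf_dna(len, min(max(110L, len %/% 9), (len - 12L) %/% 3L - 1L))
  })

  # ---- blacklist elements --------------------------------------------
  n_bl_elements <- max(10L, n_black)
  bl_seqs <- setNames(purrr::map_chr(rep(300L, n_bl_elements), random_dna),
                      sprintf("TE%03d", seq_len(n_bl_elements)))

  # ---- novel transcripts ---------------------------------------------
  novel_ids <- sprintf("NOVEL%05d", seq_len(n_novel))
  lnc_len <- function(n) pmax(200L, as.integer(round(
    rlnorm(n, config$lnc_len_meanlog, config$lnc_len_sdlog))))
  bl_intervals <- list()
  novel_rows <- vector("list", n_novel)
  neighbour_gene <- rep(NA_character_, n_novel)
  neighbour_dist <- rep(NA_integer_, n_novel)
  copies_neighbour <- rep(FALSE, n_novel)
  # neighbour placements draw distinct coding genes
  free_genes <- sample(coding_ids)
  for (i in seq_len(n_novel)) {
    cls <- classes[i]
    len <- switch(cls,
      short = sample(80:199, 1),
      long_orf = max(400L, lnc_len(1)),
      lnc_len(1)
    )
    near <- cls == "lncrna" && length(free_genes) > 0 &&
      runif(1) < config$neighbour_prob
    if (near) {
      gid <- free_genes[1]
      free_genes <- free_genes[-1]
      gsp <- coding[coding$transcript_id == gid, ]
      gap <- sample(500:8000, 1)
      start <- max(purrr::map_int(gsp$exons, ~ as.integer(max(.x[, "end"])))) + gap
      chrom <- gsp$chrom
      neighbour_gene[i] <- gid
      neighbour_dist[i] <- gap
      copies_neighbour[i] <- runif(1) < 0.5
    } else if (cls == "annot_overlap") {
      gid <- sample(coding_ids, 1)
      gsp <- coding[coding$transcript_id == gid, ]
      ex1 <- gsp$exons[[1]]
      start <- as.integer(ex1[1, "start"] + 10L)  # overlaps the first exon
      chrom <- gsp$chrom
    } else {
      pos <- next_slot()
      start <- pos$start
      chrom <- pos$chrom
    }
    n_ex <- if (cls %in% c("short", "annot_overlap")) 1L else sample(1:2, 1)
    ex <- make_exons(start, len, n_ex)
    seq <- switch(cls,
      long_orf = orf_dna(len, 110L),
      blacklist = {
        chunk <- substr(bl_seqs[[(i %% length(bl_seqs)) + 1]], 1, 60)
        repeat {  # the embedded chunk must not complete a long ORF
          s <- substr(paste0(chunk, random_noncoding_dna(max(len - 60L, 10L), 100L)),
                      1, len)
          if (longest_orf(s) < 100L) break
        }
        s
      },
      random_noncoding_dna(len, 100L)
    )
    if (cls == "blacklist") {
      bl_intervals[[length(bl_intervals) + 1]] <- tibble::tibble(
        chrom = chrom, start = max(0L, as.integer(min(ex[, "start"]) - 100L)),
        end = as.integer(max(ex[, "end"]) + 100L),
        name = names(bl_seqs)[(i %% length(bl_seqs)) + 1]
      )
    }
    novel_rows[[i]] <- tibble::tibble(
      transcript_id = novel_ids[i], gene_id = novel_ids[i],
      chrom = chrom, strand = ".", biotype = "novel",
      exons = list(ex), length = sum(ex[, "end"] - ex[, "start"]),
      sequence = seq
    )
  }
  novel <- purrr::list_rbind(novel_rows)
  blacklist_intervals <- if (length(bl_intervals) > 0) {
    dplyr::arrange(purrr::list_rbind(bl_intervals), .data$chrom, .data$start)
  } else {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   name = character())
  }

  # ---- cluster assignment and expression -----------------------------
  coding_cluster <- rep(NA_integer_, n_coding)
  n_reg_coding <- round(n_coding * config$frac_regulated_coding)
  reg_ix <- sample.int(n_coding, n_reg_coding)
  coding_cluster[reg_ix] <- rep_len(seq_len(k), n_reg_coding)[sample.int(n_reg_coding)]

  novel_cluster <- rep(NA_integer_, n_novel)
  true_ix <- which(classes == "lncrna")
  n_reg_lnc <- round(length(true_ix) * config$frac_regulated_lnc)
  reg_lnc_ix <- sample(true_ix, n_reg_lnc)
  novel_cluster[reg_lnc_ix] <- rep_len(seq_len(k), n_reg_lnc)[sample.int(n_reg_lnc)]
  # lncRNAs planted to track their neighbour adopt its pattern
  for (i in which(copies_neighbour)) {
    novel_cluster[i] <- coding_cluster[match(neighbour_gene[i], coding_ids)]
  }

  mult_for <- function(cl) {
    if (is.na(cl)) rep(1, 9) else patterns$multipliers[[cl]]
  }
  sim_fpkm <- function(base, cl) {
    mu <- base * mult_for(cl)
    mu * 10^rnorm(9, 0, config$noise_sd)
  }
  expr_rows <- matrix(0, n_coding + n_novel, 9,
                      dimnames = list(c(coding_ids, novel_ids), sample_names()))
  for (i in seq_len(n_coding)) {
    expr_rows[i, ] <- sim_fpkm(config$coding_base_fpkm, coding_cluster[i])
  }
  for (i in seq_len(n_novel)) {
    expr_rows[n_coding + i, ] <- if (classes[i] == "low_expression") {
      runif(9, 0, 0.08)
    } else {
      sim_fpkm(config$lnc_base_fpkm, novel_cluster[i])
    }
  }
  expr <- tibble::as_tibble(cbind(
    tibble::tibble(transcript_id = rownames(expr_rows)),
    tibble::as_tibble(expr_rows)
  ))

  # ---- H3K27me3 peaks -------------------------------------------------
  all_tx <- dplyr::bind_rows(coding, novel)
  spans <- transcript_spans(all_tx)
  cluster_of <- c(coding_cluster, novel_cluster)
  is_reg_lnc <- c(rep(FALSE, n_coding),
                  classes == "lncrna" & !is.na(novel_cluster))
  p_peak <- ifelse(is_reg_lnc, config$peak_assoc_prob,
                   config$peak_background_prob)
  has_peak <- runif(nrow(spans)) < p_peak
  peaks <- tibble::tibble(
    chrom = spans$chrom[has_peak],
    start = pmax(0L, spans$start[has_peak] - 200L),
    end = spans$start[has_peak] + pmax(
      300L, (spans$end[has_peak] - spans$start[has_peak]) %/% 2L),
    name = paste0("peak_", spans$transcript_id[has_peak])
  ) |> dplyr::arrange(.data$chrom, .data$start)

  # ---- catalogues ------------------------------------------------------
  go_planted <- purrr::map(seq_len(k), function(cl) {
    tibble::tibble(term = sprintf("GO:PLANTED%02d", cl),
                   gene = coding_ids[which(coding_cluster == cl)])
  })
  go_background <- purrr::map(seq_len(20), function(j) {
    tibble::tibble(term = sprintf("GO:RANDOM%02d", j),
                   gene = sample(coding_ids, sample(10:40, 1)))
  })
  go_map <- dplyr::distinct(purrr::list_rbind(c(go_planted, go_background)))
  tf_ids <- sort(sample(coding_ids, round(0.15 * n_coding)))
  meg_ids <- sort(sample(coding_ids, min(60L, n_coding)))
  peg_ids <- sort(sample(setdiff(coding_ids, meg_ids),
                         min(50L, n_coding - length(meg_ids))))

  # ---- truth table -----------------------------------------------------
  call_for <- function(cl, field) {
    if (is.na(cl)) character() else patterns[[field]][[cl]]
  }
  truth <- tibble::tibble(
    transcript_id = c(coding_ids, novel_ids),
    class = c(rep("coding", n_coding), classes),
    is_true_lncrna = c(rep(FALSE, n_coding), classes == "lncrna"),
    cluster = cluster_of,
    spatial_up = purrr::map(cluster_of, call_for, "spatial_up"),
    temporal_up = purrr::map(cluster_of, call_for, "temporal_up"),
    regulated = !is.na(cluster_of),
    has_peak = has_peak,
    neighbour_gene = c(rep(NA_character_, n_coding), neighbour_gene),
    neighbour_distance = c(rep(NA_integer_, n_coding), neighbour_dist),
    copies_neighbour = c(rep(FALSE, n_coding), copies_neighbour)
  )

  structure(
    list(
      transcripts = all_tx, expr = expr, peaks = peaks, go_map = go_map,
      tf_ids = tf_ids, meg_ids = meg_ids, peg_ids = peg_ids,
      blacklist_intervals = blacklist_intervals, blacklist_seqs = bl_seqs,
      truth = truth, patterns = patterns, config = config
    ),
    class = "endo_bundle"
  )
}

#' Write a synthetic bundle to plain-text files
#'
#' @param bundle An `endo_bundle` from [generate_bundle()].
#' @param dir Output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gtf(bundle$transcripts, p("annotation.gtf"))
  write_fasta(setNames(bundle$transcripts$sequence,
                       bundle$transcripts$transcript_id), p("transcripts.fasta"))
  write_expression(bundle$expr, p("expression.tsv"))
  write_bed(bundle$peaks, p("peaks.bed"))
  readr::write_tsv(bundle$go_map, p("go_map.tsv"), progress = FALSE)
  writeLines(bundle$tf_ids, p("tf_list.txt"))
  writeLines(bundle$meg_ids, p("meg_list.txt"))
  writeLines(bundle$peg_ids, p("peg_list.txt"))
  write_bed(bundle$blacklist_intervals, p("blacklist.bed"))
  write_fasta(bundle$blacklist_seqs, p("blacklist.fasta"))
  truth_flat <- bundle$truth |>
    dplyr::mutate(
      spatial_up = purrr::map_chr(.data$spatial_up, paste, collapse = ","),
      temporal_up = purrr::map_chr(.data$temporal_up, paste, collapse = ",")
    )
  readr::write_tsv(truth_flat, p("truth_transcripts.tsv"), progress = FALSE)
  files <- c(
    gtf = p("annotation.gtf"), fasta = p("transcripts.fasta"),
    expression = p("expression.tsv"), peaks = p("peaks.bed"),
    go_map = p("go_map.tsv"), tf = p("tf_list.txt"), meg = p("meg_list.txt"),
    peg = p("peg_list.txt"), blacklist_bed = p("blacklist.bed"),
    blacklist_fasta = p("blacklist.fasta"), truth = p("truth_transcripts.tsv")
  )
  invisible(files)
}

#' Generate qPCR tables with known fold changes
#'
#' Expression mode plants `Ct_target = Ct_reference - log2(fold)` so
#' perfect-doubling chemistry recovers `fold` exactly; ChIP mode plants
#' per-target enrichments and the Ct values that encode them relative to a
#' diluted input.
#'
#' @param config A [simulation_config()] (only the seed is used).
#' @param n_targets Number of targets.
#' @param ct_reference Reference-gene Ct (expression mode).
#' @param ct_input Input-material Ct (ChIP mode).
#' @param input_dilution Input dilution fraction (ChIP mode).
#' @return A list with tibbles `expression` (`target`, `ct_target`,
#'   `ct_reference`, `true_fold`) and `chip` (`target`, `ct_ip`,
#'   `ct_input`, `input_dilution`, `true_enrichment`, `true_fold` relative
#'   to the first target as reference).
#' @export
generate_qpcr_table <- function(config = simulation_config(), n_targets = 12L,
                                ct_reference = 25, ct_input = 24,
                                input_dilution = 0.1) {
  with_preserved_seed(config$seed + 101L, {
    fold <- 2^runif(n_targets, -3, 3)
    fold[1] <- 1
    expression <- tibble::tibble(
      target = sprintf("T%02d", seq_len(n_targets)),
      ct_target = ct_reference - log2(fold),
      ct_reference = ct_reference,
      true_fold = fold
    )
    enr <- input_dilution * 2^runif(n_targets, 0, 5)
    chip <- tibble::tibble(
      target = sprintf("T%02d", seq_len(n_targets)),
      ct_ip = ct_input - log2(enr / input_dilution),
      ct_input = ct_input,
      input_dilution = input_dilution,
      true_enrichment = enr,
      true_fold = enr / enr[1]
    )
    list(expression = expression, chip = chip)
  })
}
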