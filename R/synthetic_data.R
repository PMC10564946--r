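#' Toy genome annotation with planted motifs
#'
#' Builds a deterministic toy annotation: non-overlapping three-exon coding
#' genes alternating between strands on one chromosome, each with 5'UTR, CDS
#' and 3'UTR, plus a random genome sequence in which every designated peak
#' region carries a planted `GGACT` (a GGACH instance) on the transcript
#' strand. Even-numbered genes get a BCA transcription start (TSS adenosine
#' preceded by C on the transcript strand) so m6Am flagging is exercised;
#' odd-numbered genes get a non-A TSS.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed.
#' @return List with `transcripts` ([transcript_models]), `genome` (named
#'   character vector), and `planted_peaks` (interval tibble with `gene_id`,
#'   `peak_id`, `m6am_gene`).
#' @export
make_toy_annotation <- function(n_genes = 10, seed = 1) {
  if (n_genes < 1) abort("n_genes must be >= 1")
  set.seed(seed)
  gene_span <- 1400L
  gap <- 500L
  margin <- 100L
  glen <- margin + n_genes * (gene_span + gap) + margin
  genome_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)

  tx <- vector("list", n_genes)
  ex <- vector("list", n_genes)
  pk <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    g0 <- margin + (i - 1L) * (gene_span + gap)
    strand <- if (i %% 2 == 1) "+" else "-"
    gid <- sprintf("gene%02d", i)
    tid <- sprintf("tx%02d", i)
    tx[[i]] <- tibble(gene_id = gid, transcript_id = tid, chrom = "chr1",
                      start = g0, end = g0 + gene_span, strand = strand,
                      cds_start = g0 + 150L, cds_end = g0 + 1250L,
                      is_canonical = TRUE)
    ex[[i]] <- tibble(transcript_id = tid, chrom = "chr1",
                      start = g0 + c(0L, 500L, 1100L),
                      end = g0 + c(300L, 900L, 1400L),
                      strand = strand)
    # planted peak in the 3'-terminal exon, with a motif on the tx strand
    pk[[i]] <- tibble(chrom = "chr1", start = g0 + 1150L, end = g0 + 1350L,
                      strand = strand, gene_id = gid,
                      peak_id = sprintf("planted_%02d", i),
                      m6am_gene = i %% 2 == 0)
    motif_at <- g0 + 1200L
    motif <- if (strand == "+") c("G", "G", "A", "C", "T")
             else c("A", "G", "T", "C", "C")  # revcomp(GGACT)
    genome_chars[(motif_at + 1):(motif_at + 5)] <- motif

    tss_state <- if (i %% 2 == 0) "BCA" else "notA"
    if (strand == "+") {
      if (tss_state == "BCA") {
        genome_chars[g0 + 1] <- "A"; genome_chars[g0] <- "C"
      } else genome_chars[g0 + 1] <- "G"
    } else {
      tss <- g0 + gene_span - 1L
      if (tss_state == "BCA") {
        genome_chars[tss + 1] <- "T"; genome_chars[tss + 2] <- "G"
      } else genome_chars[tss + 1] <- "C"
    }
  }
  list(
    transcripts = transcript_models(list_rbind(tx), list_rbind(ex)),
    genome = c(chr1 = paste(genome_chars, collapse = "")),
    planted_peaks = list_rbind(pk)
  )
}

#' Simulate MeRIP IP/input coverage with planted enrichment peaks
#'
#' Poisson background over the transcribed gene spans in both tracks (near
#' zero elsewhere); IP intensity is multiplied by `enrichment_fold` inside
#' the planted peaks. Per-peak read counts and library sizes are derived from
#' the same tracks.
#'
#' @param annotation list from [make_toy_annotation()].
#' @param planted_peaks interval tibble of true peaks (default the
#'   annotation's).
#' @param enrichment_fold IP enrichment inside planted peaks (> 1 for
#'   signal; 1 gives a null dataset).
#' @param depth mean background reads per base.
#' @param seed integer seed.
#' @return List `ip`, `input` (named per-chrom count vectors), `counts`
#'   (tibble for [relative_m6a_level()]), `lib_sizes`, `truth`.
#' @export
simulate_merip <- function(annotation, planted_peaks = NULL,
                           enrichment_fold = 10, depth = 0.5, seed = 1) {
  if (enrichment_fold < 1) abort("enrichment_fold must be >= 1")
  set.seed(seed)
  peaks <- planted_peaks %||% annotation$planted_peaks
  glen <- nchar(annotation$genome[["chr1"]])
  txs <- annotation$transcripts$transcripts

  lambda_bg <- rep(0.01, glen)
  for (i in seq_len(nrow(txs))) {
    lambda_bg[(txs$start[i] + 1):txs$end[i]] <- depth
  }
  lambda_ip <- lambda_bg
  for (i in seq_len(nrow(peaks))) {
    span <- (peaks$start[i] + 1):peaks$end[i]
    lambda_ip[span] <- lambda_ip[span] * enrichment_fold
  }
  ip <- rpois(glen, lambda_ip)
  input <- rpois(glen, lambda_bg)

  counts <- map(seq_len(nrow(peaks)), function(i) {
    span <- (peaks$start[i] + 1):peaks$end[i]
    tibble(peak_id = peaks$peak_id[i], sample_id = "sim",
           ip_count = sum(ip[span]), input_count = sum(input[span]),
           peak_length = length(span))
  }) |> list_rbind()

  list(
    ip = list(chr1 = ip), input = list(chr1 = input),
    counts = counts,
    lib_sizes = tibble(sample_id = "sim", ip_lib = sum(ip),
                       input_lib = sum(input)),
    truth = peaks
  )
}

#' Simulate an m6A cohort with planted subtype and driver structure
#'
#' Emulates the statistical structure of a paired tumor/normal MeRIP cohort:
#' log-normal baseline m6A levels per peak; planted tumor-vs-normal effects
#' on `n_hyper`/`n_hypo` peaks; a planted two-subtype split of the tumors in
#' which S2 samples carry an extra multiplicative `subtype_effect` on the
#' hyper peaks; a driver RBP whose per-sample expression is mixed into the
#' hyper-peak levels of tumor samples so that it explains `driver_effect` of
#' their within-subtype residual variance; independent clinical covariates;
#' and exponential survival with a shorter median in S2. All truth labels are
#' returned.
#'
#' With an active driver (`driver_effect > 0`) the subtype effect is mediated
#' by the driver, mirroring a regulator whose over-expression defines the
#' hypermethylated subtype: S2 tumors express the driver higher by
#' `log2(subtype_effect)` divided by the mixing coefficient, so the planted
#' S2 level shift arrives entirely through the driver term. With
#' `driver_effect = 0` the driver is drawn exactly like the decoy RBPs
#' (exchangeable null) and the subtype effect is applied directly to the
#' levels.
#'
#' @param n_pairs patients with paired tumor + normal samples.
#' @param n_extra_tumor additional unpaired tumor samples.
#' @param n_peaks total peaks.
#' @param n_hyper,n_hypo planted differential peak counts.
#' @param tumor_effect multiplicative tumor/normal effect on planted peaks.
#' @param subtype_fraction fraction of tumors assigned to S2.
#' @param subtype_effect extra multiplicative effect on hyper peaks in S2.
#' @param n_rbps number of RBP expression columns (first one is the driver).
#' @param driver_effect fraction of residual hyper-peak variance explained by
#'   the driver in tumor samples (in [0, 1)).
#' @param noise_sd residual log2 s.d. of levels.
#' @param median_s1,median_s2 median survival (months) of the two subtypes.
#' @param seed integer seed.
#' @return List `levels` (long tibble), `samples`, `pairs`, `rbp_expr` (wide
#'   tibble), `clinical`, `survival`, `truth`.
#' @export
simulate_cohort <- function(n_pairs = 33, n_extra_tumor = 32, n_peaks = 2000,
                            n_hyper = 195, n_hypo = 93, tumor_effect = 2,
                            subtype_fraction = 0.4, subtype_effect = 2,
                            n_rbps = 30, driver_effect = 0.5, noise_sd = 0.25,
                            median_s1 = 11.2, median_s2 = 6.6, seed = 1) {
  if (driver_effect < 0 || driver_effect >= 1) {
    abort("driver_effect must be in [0, 1)")
  }
  set.seed(seed)
  n_tumor <- n_pairs + n_extra_tumor
  tumor_ids <- sprintf("T%02d", seq_len(n_tumor))
  normal_ids <- sprintf("N%02d", seq_len(n_pairs))
  all_ids <- c(tumor_ids, normal_ids)

  peak_ids <- sprintf("peak_%04d", seq_len(n_peaks))
  hyper <- peak_ids[seq_len(n_hyper)]
  hypo <- peak_ids[n_hyper + seq_len(n_hypo)]

  n_s2 <- round(subtype_fraction * n_tumor)
  subtype <- sample(c(rep("S2", n_s2), rep("S1", n_tumor - n_s2)))
  names(subtype) <- tumor_ids

  # When the driver is active, the subtype effect on hyper peaks is mediated
  # by the driver: S2 tumors express the driver higher by delta, and the
  # planted level shift log2(subtype_effect) = b * delta arrives through the
  # mixing term. With driver_effect = 0 the driver is exchangeable with the
  # decoys and the subtype effect is applied directly.
  driver_expr <- rnorm(length(all_ids))
  names(driver_expr) <- all_ids
  b <- if (driver_effect > 0) {
    noise_sd * sqrt(driver_effect / (1 - driver_effect))
  } else 0
  if (b > 0) {
    delta <- log2(subtype_effect) / b
    s2_set <- tumor_ids[subtype == "S2"]
    driver_expr[s2_set] <- driver_expr[s2_set] + delta
  }

  mu <- rnorm(n_peaks, mean = 1, sd = 0.5)  # log2 baseline per peak
  lvl <- matrix(rnorm(n_peaks * length(all_ids), sd = noise_sd),
                nrow = n_peaks, dimnames = list(peak_ids, all_ids))
  lvl <- lvl + mu
  is_tum <- all_ids %in% tumor_ids
  lvl[hyper, is_tum] <- lvl[hyper, is_tum] + log2(tumor_effect)
  lvl[hypo, is_tum] <- lvl[hypo, is_tum] - log2(tumor_effect)
  if (b > 0) {
    lvl[hyper, tumor_ids] <- lvl[hyper, tumor_ids] +
      b * matrix(driver_expr[tumor_ids], nrow = length(hyper),
                 ncol = n_tumor, byrow = TRUE)
  } else {
    s2_ids <- tumor_ids[subtype == "S2"]
    lvl[hyper, s2_ids] <- lvl[hyper, s2_ids] + log2(subtype_effect)
  }
  levels_long <- tibble(
    peak_id = rep(peak_ids, times = length(all_ids)),
    sample_id = rep(all_ids, each = n_peaks),
    m6a_level = 2^as.vector(lvl)
  )

  rbp_names <- sprintf("RBP%02d", seq_len(n_rbps))
  expr <- matrix(rnorm(length(all_ids) * n_rbps), nrow = length(all_ids),
                 dimnames = list(all_ids, rbp_names))
  expr[, 1] <- driver_expr
  rbp_expr <- as_tibble(expr) |> mutate(sample_id = all_ids, .before = 1)

  samples <- tibble(
    sample_id = all_ids,
    patient = c(sprintf("P%02d", seq_len(n_tumor)),
                sprintf("P%02d", seq_len(n_pairs))),
    tissue = c(rep("tumor", n_tumor), rep("normal", n_pairs)),
    pair_id = c(ifelse(seq_len(n_tumor) <= n_pairs,
                       sprintf("pair%02d", seq_len(n_tumor)), NA),
                sprintf("pair%02d", seq_len(n_pairs)))
  )
  pairs <- tibble(pair_id = sprintf("pair%02d", seq_len(n_pairs)),
                  tumor = tumor_ids[seq_len(n_pairs)],
                  normal = normal_ids)

  clinical <- tibble(
    sample_id = tumor_ids,
    sex = sample(c("M", "F"), n_tumor, replace = TRUE),
    smoking = sample(c("yes", "no"), n_tumor, replace = TRUE),
    drinking = sample(c("yes", "no"), n_tumor, replace = TRUE),
    stage = sample(c("I", "II", "III", "IV"), n_tumor, replace = TRUE),
    differentiation = sample(c("well", "moderate", "poor"), n_tumor,
                             replace = TRUE),
    lymph_node = sample(c("pos", "neg"), n_tumor, replace = TRUE)
  )

  haz <- ifelse(subtype == "S2", log(2) / median_s2, log(2) / median_s1)
  t_event <- rexp(n_tumor, rate = haz)
  t_cens <- rexp(n_tumor, rate = log(2) / 36)
  survival_tbl <- tibble(
    sample_id = tumor_ids,
    time = pmax(pmin(t_event, t_cens), 0.1),
    event = as.integer(t_event <= t_cens),
    endpoint = "PFS"
  )

  list(
    levels = levels_long, samples = samples, pairs = pairs,
    rbp_expr = rbp_expr, clinical = clinical, survival = survival_tbl,
    truth = list(hyper_peaks = hyper, hypo_peaks = hypo,
                 subtype = tibble(sample_id = tumor_ids,
                                  subtype = unname(subtype)),
                 driver = rbp_names[1], driver_effect = driver_effect)
  )
}

#' Simulate DRB-release GRO-seq coverage with known elongation rates
#'
#' Per gene and release time, coverage is Poisson-sampled from a Gaussian
#' wavefront centered `rate x time` downstream of the TSS on top of a basal
#' gradient decaying from the TSS. Each gene sits on its own contig; genes
#' alternate strands (minus-strand genes run right-to-left).
#'
#' @param n_genes number of genes.
#' @param rates true rates in kb/min (default drawn U(0.5, 4)).
#' @param times release times in minutes.
#' @param wave_sd s.d. of the Gaussian wavefront (bp).
#' @param amp wave amplitude (reads/base at the crest).
#' @param basal basal coverage at the TSS.
#' @param upstream,downstream profile window (bp).
#' @param seed integer seed.
#' @return List `coverage` (per-time named list of per-contig vectors),
#'   `genes`, `truth` (tibble `gene_id`, `rate_kb_per_min`).
#' @export
simulate_groseq <- function(n_genes = 50, rates = NULL, times = c(10, 25),
                            wave_sd = 1000, amp = 5, basal = 0.5,
                            upstream = 10000, downstream = 120000, seed = 1) {
  set.seed(seed)
  if (is.null(rates)) rates <- runif(n_genes, 0.5, 4)
  if (any(rates <= 0)) abort("rates must be > 0")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  clen <- upstream + downstream
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  strands <- rep(c("+", "-"), length.out = n_genes)

  genes <- tibble(
    gene_id = gene_ids,
    chrom = gene_ids,
    tss = ifelse(strands == "+", upstream, downstream - 1L),
    strand = strands
  )
  x_rel <- seq(0, downstream - 1)  # TSS-relative transcribed positions
  coverage <- map(times, function(t) {
    tracks <- map(seq_len(n_genes), function(i) {
      lam_body <- basal * exp(-x_rel / 6e4) +
        amp * exp(-(x_rel - rates[i] * t * 1000)^2 / (2 * wave_sd^2))
      lam <- numeric(clen)
      if (strands[i] == "+") {
        lam[(upstream + 1):clen] <- lam_body
      } else {
        lam[1:downstream] <- rev(lam_body)
      }
      rpois(clen, lam)
    })
    setNames(tracks, gene_ids)
  })
  names(coverage) <- as.character(times)

  list(coverage = coverage, genes = genes,
       truth = tibble(gene_id = gene_ids, rate_kb_per_min = rates))
}

#' Simulate CIMS mutation tables with planted m6A sites
#'
#' True m6A sites emit C>T records at the +1 position of the adenosine (in
#' transcript orientation) with mutation fraction drawn at or below 0.5.
#' Decoys cover every rejection branch: SNP-flagged but otherwise valid
#' records, mutation fractions above 0.5, wrong substitution classes, and
#' C>T records whose upstream transcript base is not adenosine.
#'
#' @param n_true planted m6A sites.
#' @param n_decoy_each decoys per decoy class (4 classes).
#' @param seed integer seed.
#' @return List `records`, `genome`, `truth` (tibble of true adenosine
#'   positions).
#' @export
simulate_cims <- function(n_true = 100, n_decoy_each = 50, seed = 1) {
  set.seed(seed)
  n_slots <- n_true + 4 * n_decoy_each
  slot_w <- 10L
  glen <- (n_slots + 2) * slot_w
  genome_chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  slots <- sample(seq_len(n_slots))  # shuffle genomic order of classes
  slot_pos <- function(j) (slots[j] + 0L) * slot_w + 5L  # 0-based center

  draw_km <- function(valid_frac) {
    k <- sample(10:100, 1)
    m <- if (valid_frac) sample(seq_len(max(floor(k / 2), 1)), 1)
         else sample(seq(floor(k / 2) + 1, k), 1)
    c(k = k, m = m)
  }
  plant_context <- function(a_pos, strand, a_base_ok = TRUE) {
    # write the A (or a decoy base) and the mutated C on the chosen strand
    if (strand == "+") {
      genome_chars[a_pos + 1] <<- if (a_base_ok) "A" else "G"
      genome_chars[a_pos + 2] <<- "C"
      a_pos + 1L  # mutation position (0-based)
    } else {
      genome_chars[a_pos + 1] <<- if (a_base_ok) "T" else "C"
      genome_chars[a_pos] <<- "G"   # complement of C
      a_pos - 1L
    }
  }

  recs <- vector("list", n_slots)
  truth <- vector("list", n_slots)
  j <- 0
  add_rec <- function(class) {
    j <<- j + 1
    a_pos <- slot_pos(j)
    strand <- sample(c("+", "-"), 1)
    valid_frac <- class != "high_mk"
    a_ok <- class != "not_a"
    mut_pos <- plant_context(a_pos, strand, a_ok)
    km <- draw_km(valid_frac)
    ref <- "C"; alt <- "T"
    if (class == "wrong_sub") { ref <- "G"; alt <- "A" }
    recs[[j]] <<- tibble(
      chrom = "chr1", pos = mut_pos, strand = strand, ref = ref, alt = alt,
      k = km[["k"]], m = km[["m"]], is_known_snp = class == "snp",
      class = class
    )
    if (class == "true") {
      truth[[j]] <<- tibble(chrom = "chr1", pos = a_pos, strand = strand)
    }
  }
  for (i in seq_len(n_true)) add_rec("true")
  for (cls in c("snp", "high_mk", "wrong_sub", "not_a")) {
    for (i in seq_len(n_decoy_each)) add_rec(cls)
  }

  list(records = list_rbind(recs),
       genome = c(chr1 = paste(genome_chars, collapse = "")),
       truth = list_rbind(truth[!map_lgl(truth, is.null)]))
}
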