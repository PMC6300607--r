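#' Configuration for the splicing-data simulator
#'
#' Bundles and validates the parameters of the synthetic splicing
#' experiment: gene-model geometry, the number of programmed events per
#' alternative-splicing category, the usage-odds effect size applied to
#' programmed junctions in the treated condition, the count model
#' (mean read depth per junction, negative-binomial dispersion, Dirichlet
#' concentration of per-sample usage variability) and the two-group
#' design. Defaults emulate a biological-triplicate two-condition
#' experiment (3 vs 3) at moderate depth.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene
#'   (min >= 3 when any event is programmed).
#' @param exon_len,intron_len Length ranges in bp.
#' @param n_es,n_ei,n_ir,n_a5ss,n_a3ss,n_ate Programmed event counts per
#'   category, each on its own gene.
#' @param ri_fraction Fraction of non-event genes given a
#'   retained-intron companion transcript.
#' @param effect_size Usage-odds multiplier (> 0) applied to programmed
#'   junctions in treated samples (direction per category: usage falls
#'   for ES and IR, rises for EI/A5SS/A3SS/ATE); 1 = null.
#' @param depth Mean reads per junction.
#' @param nb_dispersion Negative-binomial dispersion of junction counts.
#' @param dirichlet_conc Dirichlet concentration of per-sample usage
#'   proportions (larger = less biological usage variability).
#' @param n_control,n_treated Samples per condition.
#' @param seed Master random seed (integer).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 60, exons_per_gene = c(4L, 8L),
                       exon_len = c(80L, 300L), intron_len = c(200L, 2000L),
                       n_es = 0L, n_ei = 0L, n_ir = 0L, n_a5ss = 0L,
                       n_a3ss = 0L, n_ate = 0L, ri_fraction = 0.1,
                       effect_size = 4, depth = 100, nb_dispersion = 0.05,
                       dirichlet_conc = 50, n_control = 3L, n_treated = 3L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len = as.integer(exon_len),
              intron_len = as.integer(intron_len),
              n_es = as.integer(n_es), n_ei = as.integer(n_ei),
              n_ir = as.integer(n_ir), n_a5ss = as.integer(n_a5ss),
              n_a3ss = as.integer(n_a3ss), n_ate = as.integer(n_ate),
              ri_fraction = ri_fraction, effect_size = effect_size,
              depth = depth, nb_dispersion = nb_dispersion,
              dirichlet_conc = dirichlet_conc,
              n_control = as.integer(n_control),
              n_treated = as.integer(n_treated), seed = as.integer(seed))
  n_events <- with(cfg, n_es + n_ei + n_ir + n_a5ss + n_a3ss + n_ate)
  if (any(c(cfg$n_es, cfg$n_ei, cfg$n_ir, cfg$n_a5ss, cfg$n_a3ss,
            cfg$n_ate) < 0L)) {
    abort("programmed event counts must be non-negative")
  }
  if (n_events > cfg$n_genes) {
    abort("more programmed events than genes: each event needs its own gene")
  }
  if (n_events > 0L && cfg$exons_per_gene[1] < 3L) {
    abort("programmed events require genes with at least 3 exons")
  }
  if (cfg$effect_size <= 0) abort("effect size must be positive")
  if (cfg$intron_len[1] < 160L && cfg$n_ate > 0L) {
    abort("alternative-last-exon events need introns of at least 160 bp")
  }
  if (cfg$n_control < 1L || cfg$n_treated < 1L) {
    abort("both conditions need at least one sample")
  }
  structure(cfg, class = "sim_config")
}

stable_hash <- function(seed, id) {
  h <- 0
  for (code in utf8ToInt(id)) h <- (h * 31 + code) %% 2147483647
  as.integer((seed * 48271 + h) %% 2147483647)
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a gene annotation with programmed event geometry
#'
#' Generates multi-exon gene models: every gene gets a canonical
#' transcript; genes hosting programmed events additionally get the
#' geometry their category needs — a skip-variant transcript (ES/EI, so
#' an in-between exon exists), a retained-intron companion transcript
#' whose splice sites flank the programmed junction (IR), an
#' alternative-last-exon transcript (ATE). A5SS/A3SS events use a
#' junction at a *novel* donor/acceptor inside an exon, paired with an
#' annotated partner site; the alternative site is deliberately left out
#' of the annotation (an annotated alternative site could never satisfy
#' the unannotated-donor/acceptor rule) and lives in the truth table
#' only. A configurable fraction of background genes also receives a
#' retained-intron companion. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `models` (a `gene_models`), and `truth`: tibble of
#'   programmed junctions (`gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `category`, `odds_ratio`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  categories <- rep(c("ES", "EI", "IR", "A5SS", "A3SS", "ATE"),
                    times = c(cfg$n_es, cfg$n_ei, cfg$n_ir, cfg$n_a5ss,
                              cfg$n_a3ss, cfg$n_ate))
  exon_rows <- list()
  biotype_rows <- list()
  truth_rows <- list()
  offset <- 1L
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%04d", g)
    category <- if (g <= length(categories)) categories[g] else NA_character_
    strand <- sample(c("+", "-"), 1)
    n_ex <- rint(1, cfg$exons_per_gene)
    ex_len <- rint(n_ex, cfg$exon_len)
    in_len <- rint(n_ex - 1L, cfg$intron_len)
    if (identical(category, "ATE")) in_len <- pmax(in_len, 160L)
    starts <- offset + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len - 1L
    add_tx <- function(tid, s, e, biotype) {
      exon_rows[[length(exon_rows) + 1L]] <<-
        tibble(chrom = "chr1", start = as.integer(s), end = as.integer(e),
               strand = strand, gene_id = gid, transcript_id = tid)
      biotype_rows[[length(biotype_rows) + 1L]] <<-
        tibble(transcript_id = tid, biotype = biotype)
    }
    add_truth <- function(start, end, category, odds) {
      truth_rows[[length(truth_rows) + 1L]] <<-
        tibble(gene_id = gid, chrom = "chr1", strand = strand,
               start = as.integer(start), end = as.integer(end),
               category = category, odds_ratio = odds)
    }
    t1 <- paste0(gid, ".T1")
    t2 <- paste0(gid, ".T2")
    add_tx(t1, starts, ends, "protein_coding")
    e <- cfg$effect_size

    if (identical(category, "ES") || identical(category, "EI")) {
      k <- if (n_ex == 3L) 2L else sample(2:(n_ex - 1L), 1)
      add_tx(t2, starts[-k], ends[-k], "protein_coding")
      add_truth(ends[k - 1L] + 1L, starts[k + 1L] - 1L, category,
                if (category == "ES") 1 / e else e)
    } else if (identical(category, "IR")) {
      # retain intron r; the programmed junction is the adjacent intron
      # r+1, whose boundary sites the companion transcript still uses
      r <- if (n_ex == 3L) 1L else sample(1:(n_ex - 2L), 1)
      s2 <- starts[-(r + 1L)]
      e2 <- ends[-r]
      add_tx(t2, s2, e2, sample(ir_biotypes(), 1))
      add_truth(ends[r + 1L] + 1L, starts[r + 2L] - 1L, "IR", 1 / e)
    } else if (identical(category, "A5SS") || identical(category, "A3SS")) {
      i <- if (n_ex == 3L) 1L else sample(1:(n_ex - 2L), 1)
      shift_left <- if (category == "A5SS") strand == "+" else strand == "-"
      if (shift_left) {
        delta <- sample(10:min(40L, ex_len[i] - 20L), 1)
        add_truth(ends[i] - delta + 1L, starts[i + 1L] - 1L, category, e)
      } else {
        delta <- sample(10:min(40L, ex_len[i + 1L] - 20L), 1)
        add_truth(ends[i] + 1L, starts[i + 1L] + delta - 1L, category, e)
      }
    } else if (identical(category, "ATE")) {
      k <- which.max(in_len)
      alt_len <- 80L
      gap <- (in_len[k] - alt_len) %/% 2L
      alt_start <- ends[k] + gap
      alt_end <- alt_start + alt_len - 1L
      if (strand == "+") {
        add_tx(t2, c(starts[1:k], alt_start), c(ends[1:k], alt_end),
               "protein_coding")
        add_truth(ends[k] + 1L, alt_start - 1L, "ATE", e)
      } else {
        add_tx(t2, c(alt_start, starts[(k + 1L):n_ex]),
               c(alt_end, ends[(k + 1L):n_ex]), "protein_coding")
        add_truth(alt_end + 1L, starts[k + 1L] - 1L, "ATE", e)
      }
    } else if (is.na(category) && n_ex >= 3L &&
               runif(1) < cfg$ri_fraction) {
      r <- if (n_ex == 3L) 1L else sample(1:(n_ex - 2L), 1)
      add_tx(t2, starts[-(r + 1L)], ends[-r], "retained_intron")
    }
    offset <- ends[n_ex] + 10000L
  }
  if (length(exon_rows) == 0L) {
    return(list(models = gene_models(empty_exon_tbl()[0, 1:6]),
                truth = empty_truth()))
  }
  models <- gene_models(list_rbind(exon_rows), list_rbind(biotype_rows))
  truth <- if (length(truth_rows)) list_rbind(truth_rows) else empty_truth()
  list(models = models, truth = truth)
}

empty_truth <- function() {
  tibble(gene_id = character(), chrom = character(), strand = character(),
         start = integer(), end = integer(), category = character(),
         odds_ratio = numeric())
}

# Shift a usage proportion by a factor on the odds scale, renormalising
# the remaining proportions.
shift_odds <- function(p, idx, odds) {
  pi0 <- p[idx]
  pi1 <- odds * pi0 / (odds * pi0 + (1 - pi0))
  p[-idx] <- p[-idx] * (1 - pi1) / (1 - pi0)
  p[idx] <- pi1
  p
}

# Shift usage odds within a local competition block: the programmed
# junction and the junctions sharing one of its splice sites trade mass
# among themselves (the splicing decision is local), junctions outside
# the block keep their weights. `x` is the programmed junction's share
# of the block.
shift_odds_local <- function(w, idx, prt_idx, x, odds) {
  x1 <- odds * x / (odds * x + (1 - x))
  block_total <- sum(w[c(idx, prt_idx)])
  w[idx] <- block_total * x1
  w[prt_idx] <- w[prt_idx] * (1 - x1) / (1 - x)
  w
}

#' Simulate junction counts with programmed usage shifts
#'
#' For every gene, draws an expression level (log-normal around
#' `depth x n_junctions`), per-sample usage proportions over the gene's
#' junctions (Dirichlet around the gene's base usage), and
#' negative-binomial junction counts. In treated samples the programmed
#' junction's usage odds are multiplied by its `odds_ratio`, with the
#' remaining junctions renormalised. The junction catalogue is the union
#' of annotated introns and programmed (possibly novel) truth junctions.
#' Per-gene random substreams are derived from the master seed by stable
#' hashing of the gene id, so adding genes does not perturb existing
#' ones.
#'
#' @param models A `gene_models` from [simulate_annotation()].
#' @param truth The truth tibble from [simulate_annotation()].
#' @param cfg The same [sim_config()].
#' @return List with `matrix` (a gene-assigned `junction_matrix`) and
#'   `truth`: the full junction catalogue with `category` (`NA` for
#'   background junctions), `odds_ratio` and `base_usage`.
#' @export
simulate_counts <- function(models, truth, cfg) {
  stopifnot(inherits(models, "gene_models"), inherits(cfg, "sim_config"))
  index <- build_splice_index(models)
  catalog <- index$introns |>
    distinct(.data$gene_id, .data$chrom, .data$strand, .data$start, .data$end)
  catalog <- bind_rows(
    catalog,
    select(truth, "gene_id", "chrom", "strand", "start", "end")
  ) |>
    distinct(.data$gene_id, .data$chrom, .data$strand, .data$start,
             .data$end) |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand)

  sample_ids <- c(sprintf("control_%d", seq_len(cfg$n_control)),
                  sprintf("treated_%d", seq_len(cfg$n_treated)))
  condition <- rep(c("control", "treated"), c(cfg$n_control, cfg$n_treated))
  is_trt <- condition == "treated"

  counts <- matrix(0L, nrow = nrow(catalog), ncol = length(sample_ids))
  base_usage <- rep(NA_real_, nrow(catalog))
  truth_key <- paste(truth$gene_id, truth$start, truth$end)
  cat_key <- paste(catalog$gene_id, catalog$start, catalog$end)

  for (gid in unique(catalog$gene_id)) {
    rows <- which(catalog$gene_id == gid)
    J <- length(rows)
    set.seed(stable_hash(cfg$seed, gid))
    w <- rgamma(J, shape = 4, rate = 1)
    prog <- which(cat_key[rows] %in% truth_key)
    gj <- catalog[rows, , drop = FALSE]
    if (length(prog) > 0L && J > 1L) {
      # give each programmed junction a workable baseline share: of its
      # local competition block when it has partner junctions, of the
      # gene otherwise
      shares <- list()
      for (pp in prog) {
        prt_idx <- which(
          (gj$start == gj$start[pp] | gj$end == gj$end[pp]) &
            seq_len(J) != pp)
        orr_pp <- truth$odds_ratio[match(cat_key[rows][pp], truth_key)]
        if (length(prt_idx) > 0L) {
          # a junction programmed to gain usage is the minority splice
          # choice at baseline; one programmed to lose it is the majority
          x <- if (orr_pp > 1) runif(1, 0.15, 0.35) else runif(1, 0.4, 0.6)
          w[pp] <- sum(w[prt_idx]) * x / (1 - x)
          # the event's locus carries a major share of the gene's
          # junction output
          block <- c(pp, prt_idx)
          rest <- sum(w[-block])
          if (rest > 0) {
            b <- runif(1, 0.5, 0.7)
            w[block] <- w[block] * (b / (1 - b)) * rest / sum(w[block])
          }
        } else {
          x <- runif(1, 0.25, 0.45)
          w[pp] <- sum(w[-pp]) * x / (1 - x)
        }
        shares[[as.character(pp)]] <- list(prt_idx = prt_idx, x = x)
      }
      w_shift <- w
      for (pp in prog) {
        # the splicing decision is local: the programmed junction trades
        # usage with the junctions sharing one of its splice sites;
        # without partners the shift is against the rest of the gene
        orr <- truth$odds_ratio[match(cat_key[rows][pp], truth_key)]
        sh <- shares[[as.character(pp)]]
        if (length(sh$prt_idx) > 0L) {
          w_shift <- shift_odds_local(w_shift, pp, sh$prt_idx, sh$x, orr)
        } else {
          w_shift[pp] <- w_shift[pp] * orr
        }
      }
    } else {
      w_shift <- w
    }
    p_base <- w / sum(w)
    base_usage[rows] <- p_base
    p_shift <- w_shift / sum(w_shift)
    mu_total <- rlnorm(1, meanlog = log(cfg$depth * J) - 0.125, sdlog = 0.5)
    for (s in seq_along(sample_ids)) {
      target <- if (is_trt[s]) p_shift else p_base
      gam <- rgamma(J, shape = cfg$dirichlet_conc * target)
      if (sum(gam) <= 0) gam <- target
      p_s <- gam / sum(gam)
      # negative-binomial expression noise lives at the gene level and
      # cancels in usage proportions; junction counts are multinomial
      # given the gene total, so each junction count is marginally
      # NB(depth x proportion) while usage noise is Dirichlet-multinomial
      total_s <- rnbinom(1, mu = mu_total, size = 1 / cfg$nb_dispersion)
      counts[rows, s] <- as.integer(stats::rmultinom(1, total_s, p_s))
    }
  }

  junctions <- select(catalog, "chrom", "start", "end", "strand")
  junctions$gene_id <- catalog$gene_id
  samples <- tibble(sample_id = sample_ids, condition = condition)
  m <- new_junction_matrix(junctions, counts, samples)

  full_truth <- catalog |>
    mutate(category = truth$category[match(cat_key, truth_key)],
           odds_ratio = truth$odds_ratio[match(cat_key, truth_key)],
           base_usage = base_usage)
  list(matrix = m, truth = full_truth)
}

#' Simulate a complete splicing dataset
#'
#' Convenience wrapper running [simulate_annotation()] then
#' [simulate_counts()], with generated-truth consistency checks: every
#' programmed ES/EI junction has an in-between exon in the emitted
#' annotation, and every programmed IR junction shares a boundary site
#' with an emitted retained-intron/NMD transcript.
#'
#' @param cfg A [sim_config()].
#' @return List with `models`, `index`, `matrix`, `truth`.
#' @export
simulate_splicing_dataset <- function(cfg) {
  ann <- simulate_annotation(cfg)
  index <- build_splice_index(ann$models)
  check_truth_consistency(ann$truth, index)
  cnt <- simulate_counts(ann$models, ann$truth, cfg)
  list(models = ann$models, index = index, matrix = cnt$matrix,
       truth = cnt$truth)
}

check_truth_consistency <- function(truth, index) {
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    if (row$category %in% c("ES", "EI")) {
      if (nrow(find_in_between_exons(row, index)) == 0L) {
        abort(paste0("truth inconsistency: programmed ", row$category,
                     " junction without an in-between exon in ", row$gene_id))
      }
    }
    if (row$category == "IR") {
      bt <- c(site_biotypes(row$gene_id, row$start - 1L, index),
              site_biotypes(row$gene_id, row$end + 1L, index))
      if (!any(bt %in% ir_biotypes())) {
        abort(paste0("truth inconsistency: programmed IR junction not on a ",
                     "retained-intron/NMD site in ", row$gene_id))
      }
    }
  }
  invisible(TRUE)
}

#' Write a simulated dataset to standard files
#'
#' Emits the annotation as GTF, one STAR-dialect `SJ.out.tab` per
#' sample, a sample-sheet CSV and the truth table as TSV.
#'
#' @param sim Result of [simulate_splicing_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gtf(sim$models, file.path(dir, "annotation.gtf"))
  m <- sim$matrix
  for (s in seq_len(nrow(m$samples))) {
    sj <- bind_cols(m$junctions[, c("chrom", "start", "end", "strand")],
                    tibble(count = m$counts[, s]))
    write_star_sj(sj, file.path(dir, paste0(m$samples$sample_id[s],
                                            ".SJ.out.tab")))
  }
  readr::write_csv(m$samples, file.path(dir, "samples.csv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Configuration for the dose-matrix simulator
#'
#' Defaults emulate an 8 x 6 two-drug dose matrix in triplicate:
#' drug A spans a 2-fold series up to 5 (plus dose 0), drug B up to
#' 312.5 (plus dose 0), with Hill-curve single-agent effects.
#'
#' @param dose_a,dose_b Dose vectors, each including 0.
#' @param hill_a,hill_b Named vectors `c(emax, ec50, h)` of monotone
#'   Hill parameters for each single agent.
#' @param interaction Constant excess effect added to every combination
#'   cell (0 = Bliss independence; positive = synergy).
#' @param noise_sd Gaussian viability noise s.d. per replicate well.
#' @param n_replicates Replicates per well.
#' @param seed Random seed.
#' @return A `dose_sim_config` list.
#' @export
sim_dose_config <- function(dose_a = c(0, 5 / 2^(6:0)),
                            dose_b = c(0, 312.5 / 2^(4:0)),
                            hill_a = c(emax = 0.5, ec50 = 0.6, h = 1.5),
                            hill_b = c(emax = 0.4, ec50 = 60, h = 1.2),
                            interaction = 0, noise_sd = 0,
                            n_replicates = 3L, seed = 1L) {
  stopifnot(0 %in% dose_a, 0 %in% dose_b,
            all(c("emax", "ec50", "h") %in% names(hill_a)),
            all(c("emax", "ec50", "h") %in% names(hill_b)),
            noise_sd >= 0, n_replicates >= 1)
  structure(list(dose_a = dose_a, dose_b = dose_b, hill_a = hill_a,
                 hill_b = hill_b, interaction = interaction,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "dose_sim_config")
}

hill_effect <- function(d, pars) {
  ifelse(d == 0, 0,
         pars[["emax"]] * d^pars[["h"]] /
           (pars[["ec50"]]^pars[["h"]] + d^pars[["h"]]))
}

#' Simulate a two-drug dose matrix with known interaction
#'
#' Single-agent effects follow Hill curves; combination effects are the
#' Bliss expectation plus a configured constant interaction, clipped to
#' `[0, 1]`. Per-replicate viability wells get Gaussian noise, are
#' averaged, and normalised to the untreated control well, exactly as a
#' measured plate would be.
#'
#' @param cfg A [sim_dose_config()].
#' @return List with `matrix` (a `dose_matrix`) and `true_excess` (the
#'   programmed excess-over-Bliss grid, 0 on the margins).
#' @export
simulate_dose_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "dose_sim_config"))
  set.seed(cfg$seed)
  ea <- hill_effect(cfg$dose_a, cfg$hill_a)
  eb <- hill_effect(cfg$dose_b, cfg$hill_b)
  comb <- outer(cfg$dose_a > 0, cfg$dose_b > 0, `&`)
  e_true <- outer(ea, eb, bliss_expected) + cfg$interaction * comb
  e_true <- pmin(pmax(e_true, 0), 1)
  viability <- 1 - e_true
  scale <- 1000
  reps <- array(0, dim = c(dim(viability), cfg$n_replicates))
  for (r in seq_len(cfg$n_replicates)) {
    reps[, , r] <- (viability + rnorm(length(viability),
                                      sd = cfg$noise_sd)) * scale
  }
  raw <- apply(reps, c(1, 2), mean)
  m <- normalize_to_control(raw, cfg$dose_a, cfg$dose_b,
                            control = raw[which(cfg$dose_a == 0),
                                          which(cfg$dose_b == 0)],
                            n_replicates = cfg$n_replicates)
  exp_grid <- outer(ea, eb, bliss_expected)
  list(matrix = m, true_excess = e_true - exp_grid)
}
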