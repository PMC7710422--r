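#' Configuration for the synthetic multi-omic cohort generator
#'
#' Defines the cohort (cancer types, gene family, background genes, group
#' sizes) and the planted effects for every omic layer. Planted effects are
#' given per gene (and, for pathway and drug effects, per pathway/drug) and
#' are applied identically in every cancer type; the expanded per-(gene,
#' cancer) registry is emitted by [generate_cohort()] as its `truth`
#' component. Absent entries mean "no planted effect".
#'
#' Defaults mirror the study conditions of the pan-cancer HIF landscape:
#' eleven cancer types with matched normals, the six-member gene family,
#' fold-change-2 differential expression, a positive copy-number dosage
#' slope, a +/-0.2 promoter-methylation beta shift with negative
#' methylation-expression coupling, per-gene mutation probabilities around
#' the reported 26%/17% marks, strong pathway-activity displacement for
#' EMT/PI3K-AKT/cell-cycle, a few drug-sensitivity correlations of
#' magnitude 0.6, and one unfavorable plus one favorable prognostic gene.
#'
#' @param cancer_types labels of the simulated cancers.
#' @param target_genes the gene family under study.
#' @param n_background_genes number of null background genes (named BG0001,
#'   ...), used for calibration checks.
#' @param n_tumor,n_normal samples per cancer (normals are barcode-matched to
#'   the first `n_normal` tumor participants); both must be >= 3.
#' @param n_cell_lines,n_drugs cell-line panel dimensions.
#' @param seed integer RNG seed; the whole bundle is a deterministic function
#'   of config + seed.
#' @param nb_dispersion global negative-binomial dispersion of counts.
#' @param de_log2fc named numeric: planted tumor-vs-normal log2 fold changes.
#' @param cnv_dosage_slope named numeric in (-1, 1): expression mean is
#'   multiplied by `1 + slope * call / 2` for copy-number call `call`.
#' @param cnv_event_rates list with `target` and `background` numeric vectors
#'   of per-sample event probabilities named `hete_amp`, `homo_amp`,
#'   `hete_del`, `homo_del`.
#' @param meth_effect named numeric: planted tumor-minus-normal mean beta
#'   shift.
#' @param meth_expr_slope named numeric: coupling of expression to the
#'   methylation noise on the logit scale (negative = methylation represses).
#' @param mut_freq named numeric: per-sample mutation probability of each
#'   family gene.
#' @param background_mut_freq mutation probability of background genes.
#' @param snv_cg_fraction fraction of simulated SNVs forced to the C>G
#'   pyrimidine class (the class the landscape reports as dominant).
#' @param pas_shift tibble with columns `gene`, `pathway`, `shift`: pathway
#'   activity displacement (sign-aware, spread over members) between
#'   expression-high and expression-low samples.
#' @param drug_rho tibble with columns `gene`, `drug`, `rho` in (-1, 1):
#'   planted expression-AUC correlations (negative = high expression is
#'   sensitive).
#' @param hazard_direction named character, values `"unfavorable"` (hazard
#'   ratio 2 for expression-high) or `"favorable"` (hazard ratio 0.5).
#' @param censoring_fraction target fraction of censored survival times.
#' @param layers which omic layers to generate; dropping layers speeds up
#'   large calibration runs.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(
    cancer_types = c(
      "THCA", "KIRP", "LIHC", "STAD", "BRCA", "COAD", "UCEC",
      "BLCA", "KIRC", "KICH", "PRAD"
    ),
    target_genes = c("HIF1A", "ARNT", "EPAS1", "ARNT2", "HIF3A", "ARNTL"),
    n_background_genes = 50L,
    n_tumor = 20L,
    n_normal = 20L,
    n_cell_lines = 300L,
    n_drugs = 30L,
    seed = 1L,
    nb_dispersion = 0.1,
    de_log2fc = c(HIF1A = 2, EPAS1 = -2, HIF3A = -2),
    cnv_dosage_slope = c(ARNT = 0.5),
    cnv_event_rates = list(
      target = c(hete_amp = 0.25, homo_amp = 0.10, hete_del = 0.15, homo_del = 0.05),
      background = c(hete_amp = 0.01, homo_amp = 0.005, hete_del = 0.01, homo_del = 0.005)
    ),
    meth_effect = c(HIF3A = 0.2, HIF1A = -0.2),
    meth_expr_slope = c(
      HIF1A = -0.5, ARNT = -0.5, EPAS1 = -0.5,
      ARNT2 = -0.5, HIF3A = -0.5, ARNTL = -0.5
    ),
    mut_freq = c(
      EPAS1 = 0.26, HIF3A = 0.26, ARNTL = 0.17,
      HIF1A = 0.10, ARNT = 0.10, ARNT2 = 0.10
    ),
    background_mut_freq = 0.02,
    snv_cg_fraction = 0.5,
    pas_shift = tibble::tibble(
      gene = c("HIF1A", "HIF3A", "ARNT"),
      pathway = c("EMT", "PI3K/AKT", "Cell Cycle"),
      shift = c(4, 4, -4)
    ),
    drug_rho = tibble::tibble(
      gene = c("EPAS1", "EPAS1", "EPAS1", "HIF3A"),
      drug = c("drug01", "drug02", "drug03", "drug04"),
      rho = c(-0.6, -0.6, -0.6, 0.6)
    ),
    hazard_direction = c(HIF1A = "unfavorable", ARNTL = "favorable"),
    censoring_fraction = 0.3,
    layers = c(
      "expression", "cnv", "methylation", "mutation", "rppa",
      "drug", "survival"
    )) {
  config <- list(
    cancer_types = cancer_types, target_genes = target_genes,
    n_background_genes = as.integer(n_background_genes),
    n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
    n_cell_lines = as.integer(n_cell_lines), n_drugs = as.integer(n_drugs),
    seed = as.integer(seed), nb_dispersion = nb_dispersion,
    de_log2fc = de_log2fc, cnv_dosage_slope = cnv_dosage_slope,
    cnv_event_rates = cnv_event_rates, meth_effect = meth_effect,
    meth_expr_slope = meth_expr_slope, mut_freq = mut_freq,
    background_mut_freq = background_mut_freq,
    snv_cg_fraction = snv_cg_fraction,
    pas_shift = tibble::as_tibble(pas_shift),
    drug_rho = tibble::as_tibble(drug_rho),
    hazard_direction = hazard_direction,
    censoring_fraction = censoring_fraction,
    layers = layers
  )
  validate_cohort_config(config)
}

validate_cohort_config <- function(config) {
  with(config, {
    if (n_tumor < 3L || n_normal < 3L) {
      stop("n_tumor and n_normal must be >= 3", call. = FALSE)
    }
    if (n_normal > n_tumor) {
      stop("n_normal must not exceed n_tumor (normals are matched)",
        call. = FALSE
      )
    }
    if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
    genes <- c(target_genes, background_gene_names(n_background_genes))
    planted <- c(
      names(de_log2fc), names(cnv_dosage_slope), names(meth_effect),
      names(meth_expr_slope), names(mut_freq), pas_shift$gene,
      drug_rho$gene, names(hazard_direction)
    )
    if (length(setdiff(planted, genes)) > 0L) {
      stop("planted gene(s) outside the gene universe: ",
        paste(setdiff(planted, genes), collapse = ", "),
        call. = FALSE
      )
    }
    if (length(cnv_dosage_slope) > 0L && any(abs(cnv_dosage_slope) >= 1)) {
      stop("cnv_dosage_slope must lie in (-1, 1)", call. = FALSE)
    }
    if (nrow(drug_rho) > 0L && any(abs(drug_rho$rho) >= 1)) {
      stop("drug_rho must lie in (-1, 1)", call. = FALSE)
    }
    if (!all(hazard_direction %in% c("favorable", "unfavorable"))) {
      stop("hazard_direction values must be 'favorable' or 'unfavorable'",
        call. = FALSE
      )
    }
    bad_pw <- setdiff(pas_shift$pathway, hallmark_pathways()$pathway)
    if (length(bad_pw) > 0L) {
      stop("unknown pathway in pas_shift: ", paste(bad_pw, collapse = ", "),
        call. = FALSE
      )
    }
  })
  structure(config, class = "cohort_config")
}

background_gene_names <- function(n) {
  if (n == 0L) character(0) else sprintf("BG%04d", seq_len(n))
}

#' Synthetic definitions of the ten hallmark pathways
#'
#' The ten cancer-hallmark pathways scored from RPPA data: apoptosis, cell
#' cycle, DNA damage response, EMT, hormone AR, hormone ER, PI3K/AKT,
#' RAS/MAPK, RTK, and TSC/mTOR. Member components are synthetic placeholders
#' (real antibody panels are proprietary annotation); each pathway carries
#' four members, and apoptosis and EMT each include one inhibitory member so
#' that sign handling is exercised.
#'
#' @return a tibble with columns `pathway`, `component`, `sign` (+1
#'   activating, -1 inhibitory).
#' @export
hallmark_pathways <- function() {
  names <- c(
    "Apoptosis", "Cell Cycle", "DNA Damage Response", "EMT",
    "Hormone AR", "Hormone ER", "PI3K/AKT", "RAS/MAPK", "RTK", "TSC/mTOR"
  )
  short <- c(
    "APO", "CC", "DDR", "EMT", "HAR", "HER", "PI3K", "MAPK", "RTK", "MTOR"
  )
  purrr::map2_dfr(names, short, function(nm, ab) {
    sign <- rep(1, 4L)
    if (nm %in% c("Apoptosis", "EMT")) sign[4L] <- -1
    tibble::tibble(
      pathway = nm,
      component = sprintf("%s.c%d", ab, 1:4),
      sign = sign
    )
  })
}

#' Generate a synthetic multi-cancer multi-omic cohort with planted effects
#'
#' Produces, per cancer type: negative-binomial expression counts for matched
#' tumor/normal samples, gene-level copy-number calls with a dosage effect on
#' expression, logit-normal promoter methylation beta values coupled to
#' expression, a somatic MAF, an RPPA protein matrix with pathway-activity
#' displacement between expression-defined groups, and right-censored
#' survival times; plus one shared cell-line panel (expression and drug AUC
#' built by a Gaussian-copula construction). The planted-effect registry is
#' returned as `truth` so every downstream stage can be scored for recovery.
#'
#' The layers share latent structure: the copy-number call and the
#' methylation noise of a sample both perturb its expected count, pathway
#' displacement is applied to the samples whose realized expression is above
#' the median, and survival hazards follow the realized expression split —
#' cross-layer correlations in the output are therefore real, not
#' coincidental. Identical config (including seed) gives an identical bundle.
#'
#' @param config a [cohort_config()].
#' @return an `omic_cohort` list: `config`, `truth` (per-layer planted-effect
#'   tibbles), `pathways`, `cohorts` (named per-cancer list with elements
#'   `counts`, `cnv`, `meth`, `rppa`, `maf`, `clinical`), and `cell_lines`
#'   (`expression`, `auc`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  genes <- c(
    config$target_genes,
    background_gene_names(config$n_background_genes)
  )
  pathways <- hallmark_pathways()
  cohorts <- lapply(config$cancer_types, function(cancer) {
    simulate_cancer(cancer, genes, config, pathways)
  })
  names(cohorts) <- config$cancer_types
  cell_lines <- if ("drug" %in% config$layers) {
    simulate_cell_lines(genes, config)
  }
  structure(
    list(
      config = config,
      truth = expand_truth(config),
      pathways = pathways,
      cohorts = cohorts,
      cell_lines = cell_lines
    ),
    class = "omic_cohort"
  )
}

# Expand the per-gene planted maps into explicit per-(gene, cancer) registries.
expand_truth <- function(config) {
  cancers <- config$cancer_types
  per_cancer <- function(named, value_col) {
    if (length(named) == 0L) {
      return(tibble::tibble(
        gene = character(), cancer = character(),
        !!value_col := numeric()
      ))
    }
    tidyr::crossing(
      tibble::tibble(gene = names(named), !!value_col := unname(named)),
      cancer = cancers
    )
  }
  list(
    de_log2fc = per_cancer(config$de_log2fc, "log2fc"),
    cnv_dosage_slope = tibble::tibble(
      gene = names(config$cnv_dosage_slope),
      slope = unname(config$cnv_dosage_slope)
    ),
    meth_effect = per_cancer(config$meth_effect, "delta_beta"),
    meth_expr_slope = tibble::tibble(
      gene = names(config$meth_expr_slope),
      slope = unname(config$meth_expr_slope)
    ),
    mut_freq = per_cancer(config$mut_freq, "freq"),
    pas_shift = tidyr::crossing(config$pas_shift, cancer = cancers),
    drug_rho = config$drug_rho,
    hazard_direction = if (length(config$hazard_direction) > 0L) {
      tidyr::crossing(
        tibble::tibble(
          gene = names(config$hazard_direction),
          direction = unname(config$hazard_direction)
        ),
        cancer = cancers
      )
    } else {
      tibble::tibble(gene = character(), direction = character(), cancer = character())
    }
  )
}

planted_value <- function(named, gene, default = 0) {
  if (length(named) == 0L) {
    return(rep(default, length(gene)))
  }
  out <- unname(named[gene])
  out[is.na(out)] <- default
  out
}

simulate_cancer <- function(cancer, genes, config, pathways) {
  G <- length(genes)
  n_t <- config$n_tumor
  n_n <- config$n_normal
  tumor_samples <- sprintf("TCGA-%s-P%04d-01A", cancer, seq_len(n_t))
  normal_samples <- sprintf("TCGA-%s-P%04d-11A", cancer, seq_len(n_n))
  is_target <- genes %in% config$target_genes

  # gene baselines: log-uniform in [2^4, 2^12]
  mu0 <- 2^stats::runif(G, 4, 12)

  # copy-number calls (tumor samples only)
  calls <- matrix(0, G, n_t, dimnames = list(genes, tumor_samples))
  if ("cnv" %in% config$layers) {
    for (g in seq_len(G)) {
      r <- config$cnv_event_rates[[if (is_target[g]) "target" else "background"]]
      calls[g, ] <- sample(
        c(1, 2, -1, -2, 0), n_t,
        replace = TRUE,
        prob = c(
          r[["hete_amp"]], r[["homo_amp"]], r[["hete_del"]],
          r[["homo_del"]], 1 - sum(r)
        )
      )
    }
  }

  # methylation: logit-normal around a per-gene baseline; tumor mean beta
  # shifted by the planted effect, clamped away from the boundaries
  base_logit <- stats::rnorm(G, stats::qlogis(0.3), 0.5)
  normal_mean <- stats::plogis(base_logit)
  tumor_mean <- pmin(pmax(
    normal_mean + planted_value(config$meth_effect, genes), 0.02
  ), 0.98)
  meth_sd <- 0.5
  logit_noise <- matrix(stats::rnorm(G * (n_t + n_n), 0, meth_sd), G)
  group_logit <- cbind(
    matrix(stats::qlogis(tumor_mean), G, n_t),
    matrix(stats::qlogis(normal_mean), G, n_n)
  )
  beta <- stats::plogis(group_logit + logit_noise)
  dimnames(beta) <- list(genes, c(tumor_samples, normal_samples))

  # expression: NB counts whose mean carries the planted fold change, the
  # copy-number dosage term and the methylation coupling (on the logit
  # noise, so tumor/normal means are perturbed symmetrically)
  lfc <- planted_value(config$de_log2fc, genes)
  slope <- planted_value(config$cnv_dosage_slope, genes)
  mslope <- planted_value(config$meth_expr_slope, genes)
  log2mu <- matrix(log2(mu0), G, n_t + n_n)
  log2mu[, seq_len(n_t)] <- log2mu[, seq_len(n_t)] + lfc +
    log2(1 + slope * calls / 2)
  if ("methylation" %in% config$layers) {
    log2mu <- log2mu + mslope * logit_noise
  }
  counts <- matrix(
    stats::rnbinom(G * (n_t + n_n),
      mu = 2^log2mu,
      size = 1 / config$nb_dispersion
    ),
    G,
    dimnames = list(genes, c(tumor_samples, normal_samples))
  )

  out <- list()
  if ("expression" %in% config$layers) {
    out$counts <- gene_sample_matrix(counts, "raw_count")
  }
  if ("cnv" %in% config$layers) {
    out$cnv <- gene_sample_matrix(calls, "cnv_call")
  }
  if ("methylation" %in% config$layers) {
    out$meth <- gene_sample_matrix(beta, "beta")
  }
  if ("mutation" %in% config$layers) {
    out$maf <- simulate_maf(genes, tumor_samples, config)
  }
  if ("rppa" %in% config$layers) {
    out$rppa <- simulate_rppa(
      counts[, tumor_samples, drop = FALSE], config, pathways
    )
  }
  if ("survival" %in% config$layers) {
    out$clinical <- simulate_survival(
      counts[, tumor_samples, drop = FALSE], config
    )
  }
  out
}

simulate_maf <- function(genes, tumor_samples, config) {
  freq <- planted_value(
    config$mut_freq, genes,
    default = config$background_mut_freq
  )
  classes <- c("Missense_Mutation", "Nonsense_Mutation", "Silent", "Frame_Shift_Del")
  recs <- list()
  for (g in seq_along(genes)) {
    if (freq[g] <= 0) next
    hit <- stats::runif(length(tumor_samples)) < freq[g]
    if (!any(hit)) next
    n_hit <- sum(hit)
    cls <- sample(classes, n_hit, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
    ref <- character(n_hit)
    alt <- character(n_hit)
    snv <- cls != "Frame_Shift_Del"
    if (any(snv)) {
      cg <- snv & stats::runif(n_hit) < config$snv_cg_fraction
      ref[cg] <- sample(c("C", "G"), sum(cg), replace = TRUE)
      alt[cg] <- ifelse(ref[cg] == "C", "G", "C")
      other <- snv & !cg
      ref[other] <- sample(c("A", "C", "G", "T"), sum(other), replace = TRUE)
      alt[other] <- vapply(
        ref[other],
        function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
        ""
      )
    }
    ref[!snv] <- sample(c("A", "C", "G", "T"), sum(!snv), replace = TRUE)
    alt[!snv] <- "-"
    recs[[length(recs) + 1L]] <- tibble::tibble(
      Hugo_Symbol = genes[g],
      Tumor_Sample_Barcode = tumor_samples[hit],
      Variant_Classification = cls,
      Reference_Allele = ref,
      Tumor_Seq_Allele2 = alt
    )
  }
  records <- if (length(recs) > 0L) {
    dplyr::bind_rows(recs)
  } else {
    tibble::tibble(
      Hugo_Symbol = character(), Tumor_Sample_Barcode = character(),
      Variant_Classification = character(), Reference_Allele = character(),
      Tumor_Seq_Allele2 = character()
    )
  }
  maf_table(records, tumor_samples)
}

simulate_rppa <- function(tumor_counts, config, pathways) {
  comps <- pathways$component
  samples <- colnames(tumor_counts)
  rppa <- matrix(
    stats::rnorm(length(comps) * length(samples)),
    length(comps),
    dimnames = list(comps, samples)
  )
  for (i in seq_len(nrow(config$pas_shift))) {
    gene <- config$pas_shift$gene[i]
    if (!gene %in% rownames(tumor_counts)) next
    members <- pathways[pathways$pathway == config$pas_shift$pathway[i], ]
    high <- median_split(tumor_counts[gene, ])
    rppa[members$component, high] <- rppa[members$component, high] +
      members$sign * config$pas_shift$shift[i] / nrow(members)
  }
  gene_sample_matrix(rppa, "protein_level")
}

simulate_survival <- function(tumor_counts, config) {
  samples <- colnames(tumor_counts)
  base_rate <- 1 / 1000 # per day
  log_hr <- rep(0, length(samples))
  for (gene in names(config$hazard_direction)) {
    if (!gene %in% rownames(tumor_counts)) next
    high <- median_split(tumor_counts[gene, ])
    hr <- if (config$hazard_direction[[gene]] == "unfavorable") 2 else 0.5
    log_hr <- log_hr + log(hr) * high
  }
  rate <- base_rate * exp(log_hr)
  death <- stats::rexp(length(samples), rate)
  cens_frac <- config$censoring_fraction
  cens_rate <- cens_frac / (1 - cens_frac) * mean(rate)
  cens <- stats::rexp(length(samples), cens_rate)
  tibble::tibble(
    barcode = samples,
    time = pmin(death, cens),
    event = as.integer(death <= cens)
  )
}

simulate_cell_lines <- function(genes, config) {
  L <- config$n_cell_lines
  lines <- sprintf("CL%04d", seq_len(L))
  drugs <- sprintf("drug%02d", seq_len(config$n_drugs))
  z <- matrix(stats::rnorm(length(genes) * L), length(genes),
    dimnames = list(genes, lines)
  )
  auc <- matrix(stats::rnorm(length(drugs) * L), length(drugs),
    dimnames = list(drugs, lines)
  )
  for (i in seq_len(nrow(config$drug_rho))) {
    gene <- config$drug_rho$gene[i]
    drug <- config$drug_rho$drug[i]
    if (!gene %in% genes || !drug %in% drugs) next
    rho <- config$drug_rho$rho[i]
    auc[drug, ] <- rho * z[gene, ] + sqrt(1 - rho^2) * stats::rnorm(L)
  }
  list(
    expression = gene_sample_matrix(8 + z, "normalized_expression"),
    auc = gene_sample_matrix(auc, "drug_auc")
  )
}

#' @export
print.omic_cohort <- function(x, ...) {
  cat(
    "<omic_cohort> ", length(x$cohorts), " cancer type(s), ",
    length(x$config$target_genes), " target + ",
    x$config$n_background_genes, " background genes, layers: ",
    paste(x$config$layers, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}
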