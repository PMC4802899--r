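#' Module specification for the synthetic generator
#'
#' A planted metabolite module: a group of metabolites that share a smooth
#' latent developmental trajectory in the condition(s) given by
#' `treatment_coupling`, with correlation strength set by `loading`.
#' `D_only` modules emulate the observation that water deficit re-organises
#' and densifies metabolite co-variation: members co-vary under deficit
#' irrigation (D) but follow weak independent trajectories under full
#' irrigation (C).
#'
#' @param module_id label for the module.
#' @param size number of member metabolites (>= 2 to produce edges).
#' @param loading coupling strength to the module latent trajectory, in (0,1].
#' @param treatment_coupling one of `"both"`, `"D_only"`, `"C_only"`.
#' @param linked_gene_count number of transcripts coupled to this module's
#'   member metabolites.
#' @return a `module_spec` list.
#' @export
module_spec <- function(module_id, size, loading = 0.9,
                        treatment_coupling = c("both", "D_only", "C_only"),
                        linked_gene_count = 0) {
  treatment_coupling <- match.arg(treatment_coupling)
  if (size < 1) stop("module size must be positive")
  if (loading <= 0 || loading > 1) stop("loading must be in (0, 1]")
  if (linked_gene_count < 0) stop("linked_gene_count must be >= 0")
  structure(list(module_id = module_id, size = as.integer(size),
                 loading = loading, treatment_coupling = treatment_coupling,
                 linked_gene_count = as.integer(linked_gene_count)),
            class = "module_spec")
}

default_modules <- function() {
  list(module_spec("mod_both", size = 8, loading = 0.9,
                   treatment_coupling = "both", linked_gene_count = 6),
       module_spec("mod_D1", size = 6, loading = 0.9,
                   treatment_coupling = "D_only", linked_gene_count = 5),
       module_spec("mod_D2", size = 5, loading = 0.9,
                   treatment_coupling = "D_only", linked_gene_count = 4))
}

#' Default PLACE-style motif library
#'
#' A small library of plant cis-regulatory elements given as IUPAC degenerate
#' consensi, covering the MYB-binding and drought/ABA-responsive elements
#' discussed in grape berry water-deficit studies plus common promoter
#' elements that serve as decoys in recovery experiments.
#'
#' @return data.frame with columns `motif_id`, `consensus`, `source`.
#' @export
default_motif_library <- function() {
  m <- c(
    MYBCORE = "CNGTTR", MYB1AT = "WAACCA", MYBPLANT = "MACCWAMC",
    MYB2CONSENSUSAT = "YAACKG", MYBCOREATCYCB1 = "AACGG",
    MYCCONSENSUSAT = "CANNTG", MYCATRD22 = "CACATG",
    DRECRTCOREAT = "RCCGAC", LTRECOREATCOR15 = "CCGAC",
    RYREPEATBNNAPA = "CATGCA", ABRELATERD1 = "ACGTG", ACGTATERD1 = "ACGT",
    GATABOX = "GATA", CAATBOX1 = "CAAT", TATABOX5 = "TTATTT",
    GT1CONSENSUS = "GRWAAW", POLLEN1LELAT52 = "AGAAA", WRKY71OS = "TGAC",
    WBOXATNPR1 = "TTGAC", ARR1AT = "NGATT", DOFCOREZM = "AAAG",
    CACTFTPPCA1 = "YACT", GTGANTG10 = "GTGA", IBOXCORE = "GATAA",
    EVENINGAT = "AAAATATCT", CIACADIANLELHC = "CAANNNNATC",
    SEF4MOTIFGM7S = "RTTTTTR", TAAAGSTKST1 = "TAAAG",
    PREATPRODH = "ACTCAT", SORLIP1AT = "GCCAC")
  data.frame(motif_id = names(m), consensus = unname(m),
             source = "PLACE", stringsAsFactors = FALSE)
}

#' Configuration of the synthetic multi-omics study
#'
#' Encodes the two-treatment developmental design: six metabolite sampling
#' stages with four biological replicates and three transcriptome stages with
#' three replicates, under full irrigation (C) and deficit irrigation (D).
#' Defaults reproduce that design with 74 metabolites and 2000 genes.
#'
#' @param seed master integer seed; all generator randomness derives from it.
#' @param stages_metab metabolite sampling stages, days after anthesis (DAA).
#' @param stages_trans transcriptome stages; must be a subset of
#'   `stages_metab`.
#' @param reps_metab,reps_trans biological replicates per (treatment, stage).
#' @param n_metabolites,n_genes numbers of features.
#' @param modules list of [module_spec()] objects; total size must not exceed
#'   `n_metabolites`.
#' @param noise_sd Gaussian noise sd on the log scale (abundances are
#'   log-normal).
#' @param background_loading trajectory amplitude, on the log scale, of
#'   features outside coupled modules. Kept at the noise scale so that chance
#'   alignment of smooth background trajectories cannot produce correlations
#'   beyond the |r| > 0.8 network gate.
#' @param treatment_effect_log2fc true log2 fold change (D/C) planted at
#'   ripening stages (>= 65 DAA); 0 gives a null treatment response.
#' @param effect_features metabolites receiving the treatment effect;
#'   `NULL` (default) uses the members of D_only modules (the
#'   drought-induced, drought-rewired compounds). For features whose C and D
#'   trajectories coincide (background, `both`-coupled members) the observed
#'   stage log2FC equals the planted value exactly in the noise-free limit;
#'   for D_only members the treatment contrast additionally contains their
#'   C/D trajectory difference.
#' @param promoter_length promoter length in nt.
#' @param regulon_size number of genes in the motif-carrying regulon.
#' @param motif_plant_rate_regulon,motif_plant_rate_background probability
#'   that each planted motif is inserted into a regulon / background
#'   promoter.
#' @param gc_content GC fraction of the random promoter background.
#' @param motif_library data.frame (`motif_id`, `consensus`, `source`).
#' @param planted_motif_ids motifs inserted into regulon promoters; must
#'   exist in `motif_library`.
#' @param de_background_rate fraction of non-linked genes flagged DE, in
#'   addition to all linked genes.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         stages_metab = c(27L, 41L, 54L, 68L, 82L, 93L),
                         stages_trans = c(41L, 68L, 93L),
                         reps_metab = 4, reps_trans = 3,
                         n_metabolites = 74, n_genes = 2000,
                         modules = default_modules(),
                         noise_sd = 0.15,
                         background_loading = 0.08,
                         treatment_effect_log2fc = 1,
                         effect_features = NULL,
                         promoter_length = 1000,
                         regulon_size = 100,
                         motif_plant_rate_regulon = 0.8,
                         motif_plant_rate_background = 0.05,
                         gc_content = 0.35,
                         motif_library = default_motif_library(),
                         planted_motif_ids = c("DRECRTCOREAT", "MYCATRD22",
                                               "RYREPEATBNNAPA"),
                         de_background_rate = 0.1) {
  cfg <- list(seed = as.integer(seed),
              stages_metab = as.integer(stages_metab),
              stages_trans = as.integer(stages_trans),
              reps_metab = as.integer(reps_metab),
              reps_trans = as.integer(reps_trans),
              n_metabolites = as.integer(n_metabolites),
              n_genes = as.integer(n_genes),
              modules = modules, noise_sd = noise_sd,
              background_loading = background_loading,
              treatment_effect_log2fc = treatment_effect_log2fc,
              effect_features = effect_features,
              promoter_length = as.integer(promoter_length),
              regulon_size = as.integer(regulon_size),
              motif_plant_rate_regulon = motif_plant_rate_regulon,
              motif_plant_rate_background = motif_plant_rate_background,
              gc_content = gc_content, motif_library = motif_library,
              planted_motif_ids = planted_motif_ids,
              de_background_rate = de_background_rate)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  counts <- c(cfg$reps_metab, cfg$reps_trans, cfg$n_metabolites, cfg$n_genes,
              cfg$promoter_length, cfg$regulon_size)
  if (any(counts < 1)) stop("configuration error: all counts must be positive")
  if (length(cfg$stages_metab) < 1 || length(cfg$stages_trans) < 1)
    stop("configuration error: at least one stage required")
  if (!all(cfg$stages_trans %in% cfg$stages_metab))
    stop("configuration error: stages_trans must be a subset of stages_metab")
  if (cfg$noise_sd < 0)
    stop("configuration error: noise_sd must be nonnegative")
  probs <- c(cfg$motif_plant_rate_regulon, cfg$motif_plant_rate_background,
             cfg$gc_content, cfg$de_background_rate)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  if (sum(vapply(cfg$modules, `[[`, integer(1), "size")) > cfg$n_metabolites)
    stop("configuration error: module sizes exceed n_metabolites")
  if (cfg$regulon_size > cfg$n_genes)
    stop("configuration error: regulon_size exceeds n_genes")
  if (length(cfg$planted_motif_ids) &&
      !all(cfg$planted_motif_ids %in% cfg$motif_library$motif_id))
    stop("configuration error: planted motifs missing from motif_library")
  widths <- nchar(cfg$motif_library$consensus)
  if (any(widths > cfg$promoter_length))
    stop("configuration error: motif longer than promoter")
  invisible(cfg)
}

## ---- latent trajectories ---------------------------------------------------

# Random smooth (cubic) trajectory over the metabolite stage grid,
# centered and scaled to sd 1 on the grid. Returned as a named vector
# indexed by stage (stages_trans is always a subset of this grid).
random_trajectory <- function(cfg, ...) {
  s <- (cfg$stages_metab - min(cfg$stages_metab)) /
    max(1, diff(range(cfg$stages_metab)))
  z <- with_seed(substream_seed(cfg$seed, ...), stats::rnorm(4))
  v <- z[1] + z[2] * s + z[3] * s^2 + z[4] * s^3
  v <- v - mean(v)
  sdv <- stats::sd(v)
  if (sdv < 1e-12) v <- s - mean(s) else v <- v / sdv # degenerate flat draw
  names(v) <- as.character(cfg$stages_metab)
  v
}

# Random smooth trajectory for features outside coupled modules, drawn from
# a degree-(up to 5) orthogonal-polynomial basis on the stage grid and then
# projected orthogonal to every module latent: background features follow
# developmental programmes genuinely distinct from the planted modules, so
# chance alignment with a module trajectory cannot mimic a planted edge.
background_trajectory <- function(cfg, latents, ...) {
  ns <- length(cfg$stages_metab)
  if (ns < 2) stop("configuration error: need >= 2 stages for trajectories")
  s <- (cfg$stages_metab - min(cfg$stages_metab)) /
    max(1, diff(range(cfg$stages_metab)))
  deg <- min(5L, ns - 1L)
  basis <- stats::poly(s, degree = deg)
  z <- with_seed(substream_seed(cfg$seed, ...), stats::rnorm(deg))
  v <- as.numeric(basis %*% z)
  v <- v - mean(v)
  for (L in latents) {
    u <- L / sqrt(sum(L^2))
    v <- v - u * sum(v * u)
  }
  sdv <- stats::sd(v)
  if (sdv < 1e-8) {
    # projection annihilated the draw (modules span the space); fall back to
    # the unprojected curve rather than a flat profile
    v <- as.numeric(basis %*% z)
    v <- v - mean(v)
    sdv <- stats::sd(v)
  }
  v <- v / sdv
  names(v) <- as.character(cfg$stages_metab)
  v
}

# Module latent trajectories, orthogonalised across modules on the stage grid
# (Gram-Schmidt in module order) so distinct modules follow genuinely distinct
# developmental programmes. The centered cubic space on the stage grid has
# dimension 3; additional modules beyond that keep their raw trajectories.
module_latents <- function(cfg) {
  mods <- cfg$modules
  if (!length(mods)) return(list())
  raw <- lapply(mods, function(m) random_trajectory(cfg, "latent", m$module_id))
  out <- list()
  basis <- NULL
  for (i in seq_along(raw)) {
    v <- raw[[i]]
    if (!is.null(basis)) {
      proj <- basis %*% crossprod(basis, v)
      resid <- v - as.numeric(proj)
      if (sqrt(sum(resid^2)) > 1e-6) v <- resid
    }
    v <- v - mean(v)
    v <- v / stats::sd(v)
    names(v) <- as.character(cfg$stages_metab)
    out[[mods[[i]]$module_id]] <- v
    u <- v / sqrt(sum(v^2))
    basis <- cbind(basis, u)
  }
  out
}

module_coupled_in <- function(mod, condition) {
  switch(mod$treatment_coupling,
         both = TRUE,
         D_only = condition == "D",
         C_only = condition == "C")
}

metabolite_ids <- function(cfg) sprintf("met_%03d", seq_len(cfg$n_metabolites))
gene_ids <- function(cfg) sprintf("gene_%04d", seq_len(cfg$n_genes))

# Assign module members (metabolites, sequential blocks) and linked genes.
module_assignment <- function(cfg) {
  mets <- metabolite_ids(cfg)
  genes <- gene_ids(cfg)
  membership <- stats::setNames(rep(NA_character_, length(mets)), mets)
  links <- list()
  m_off <- 0L; g_off <- 0L
  for (mod in cfg$modules) {
    members <- mets[(m_off + 1L):(m_off + mod$size)]
    membership[members] <- mod$module_id
    m_off <- m_off + mod$size
    if (mod$linked_gene_count > 0) {
      lg <- genes[(g_off + 1L):(g_off + mod$linked_gene_count)]
      g_off <- g_off + mod$linked_gene_count
      links[[mod$module_id]] <- data.frame(
        gene_id = lg,
        metabolite_id = rep(members, length.out = length(lg)),
        module_id = mod$module_id, stringsAsFactors = FALSE)
    }
  }
  list(membership = membership,
       links = if (length(links)) do.call(rbind, links)
               else data.frame(gene_id = character(), metabolite_id = character(),
                               module_id = character(), stringsAsFactors = FALSE))
}

sample_sheet <- function(stages, reps) {
  md <- expand.grid(replicate = seq_len(reps), stage_daa = stages,
                    treatment = c("C", "D"), stringsAsFactors = FALSE)
  md <- md[, c("treatment", "stage_daa", "replicate")]
  md$sample_id <- sprintf("%s_%d_%d", md$treatment, md$stage_daa, md$replicate)
  md[, c("sample_id", "treatment", "stage_daa", "replicate")]
}

## ---- generators ------------------------------------------------------------

#' Generate the synthetic metabolite matrix and its ground truth
#'
#' Metabolite log-abundance is `loading * L(stage, treatment)` plus the
#' planted treatment effect plus Gaussian noise; abundances are the
#' exponential, hence log-normal and strictly positive. Members of a module
#' share the module latent trajectory `L` in the conditions where the module
#' is coupled and follow weak independent trajectories elsewhere; background
#' metabolites follow weak independent trajectories shared between
#' treatments (so they are null for the stage-wise treatment comparison).
#'
#' @param cfg a [synth_config()].
#' @return list with elements `matrix` (an [omics_matrix()]) and `truth`
#'   (a `synthetic_truth` list: `module_membership`, `planted_edges`,
#'   `planted_gene_metabolite_links`, `regulon_genes`, `planted_motif_ids`,
#'   `effect_log2fc`, plus the per-condition log-mean trajectories `mu` used
#'   by [generate_transcript_matrix()]).
#' @export
generate_metabolite_matrix <- function(cfg) {
  validate_synth_config(cfg)
  mets <- metabolite_ids(cfg)
  asg <- module_assignment(cfg)
  latents <- module_latents(cfg)
  mods <- stats::setNames(cfg$modules,
                          vapply(cfg$modules, `[[`, character(1), "module_id"))
  stages_chr <- as.character(cfg$stages_metab)

  # planted treatment effects: by default D_only members induced at ripening
  eff_stages <- cfg$stages_metab[cfg$stages_metab >= 65]
  affected <- if (!is.null(cfg$effect_features)) {
    if (!all(cfg$effect_features %in% mets))
      stop("configuration error: unknown effect_features")
    cfg$effect_features
  } else {
    names(asg$membership)[!is.na(asg$membership) &
      vapply(asg$membership, function(m)
        !is.na(m) && mods[[m]]$treatment_coupling == "D_only", logical(1))]
  }
  effect <- matrix(0, nrow = length(mets), ncol = length(cfg$stages_metab),
                   dimnames = list(mets, stages_chr))
  if (cfg$treatment_effect_log2fc != 0 && length(affected) && length(eff_stages))
    effect[affected, as.character(eff_stages)] <- cfg$treatment_effect_log2fc

  # per-condition log-mean trajectories, features x stages
  mu <- list()
  for (cond in c("C", "D")) {
    mu_c <- matrix(0, nrow = length(mets), ncol = length(cfg$stages_metab),
                   dimnames = list(mets, stages_chr))
    for (f in mets) {
      mod_id <- asg$membership[[f]]
      if (!is.na(mod_id) && module_coupled_in(mods[[mod_id]], cond)) {
        mu_c[f, ] <- mods[[mod_id]]$loading * latents[[mod_id]]
      } else if (!is.na(mod_id)) {
        mu_c[f, ] <- cfg$background_loading *
          background_trajectory(cfg, latents, "traj", f, cond)
      } else {
        mu_c[f, ] <- cfg$background_loading *
          background_trajectory(cfg, latents, "traj", f)
      }
    }
    if (cond == "D") mu_c <- mu_c + log(2) * effect
    mu[[cond]] <- mu_c
  }

  md <- sample_sheet(cfg$stages_metab, cfg$reps_metab)
  values <- matrix(NA_real_, nrow = length(mets), ncol = nrow(md),
                   dimnames = list(mets, md$sample_id))
  for (f in mets) {
    eps <- with_seed(substream_seed(cfg$seed, "noise_metab", f),
                     stats::rnorm(nrow(md), 0, cfg$noise_sd))
    mu_f <- mapply(function(cond, stage) mu[[cond]][f, as.character(stage)],
                   md$treatment, md$stage_daa)
    values[f, ] <- exp(mu_f + eps)
  }

  planted <- planted_edge_table(asg$membership, mods)
  eff_df <- data.frame(
    metabolite_id = rep(rownames(effect), ncol(effect)),
    stage_daa = rep(cfg$stages_metab, each = nrow(effect)),
    log2fc = as.vector(effect), stringsAsFactors = FALSE)
  eff_df <- eff_df[eff_df$log2fc != 0, , drop = FALSE]
  rownames(eff_df) <- NULL

  genes <- gene_ids(cfg)
  linked <- asg$links$gene_id
  pool <- setdiff(genes, linked)
  regulon <- union(linked,
    with_seed(substream_seed(cfg$seed, "regulon"),
              sample(pool, max(0, cfg$regulon_size - length(linked)))))
  de_extra <- with_seed(substream_seed(cfg$seed, "de"),
    pool[stats::runif(length(pool)) < cfg$de_background_rate])
  truth <- structure(list(
    module_membership = asg$membership,
    planted_edges = planted,
    planted_gene_metabolite_links = asg$links,
    regulon_genes = sort(regulon),
    de_flags = sort(union(linked, de_extra)),
    planted_motif_ids = cfg$planted_motif_ids,
    effect_log2fc = eff_df,
    mu = mu), class = "synthetic_truth")

  list(matrix = omics_matrix(values, md), truth = truth)
}

planted_edge_table <- function(membership, mods) {
  rows <- list()
  for (mod_id in names(mods)) {
    members <- sort(names(membership)[!is.na(membership) &
                                        membership == mod_id])
    if (length(members) < 2) next
    prs <- utils::combn(members, 2)
    conds <- switch(mods[[mod_id]]$treatment_coupling,
                    both = c("C", "D"), D_only = "D", C_only = "C")
    for (cond in conds)
      rows[[paste(mod_id, cond)]] <- data.frame(
        feature_a = prs[1, ], feature_b = prs[2, ], condition = cond,
        module_id = mod_id, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(feature_a = character(), feature_b = character(),
                      condition = character(), module_id = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate the synthetic transcript matrix
#'
#' Genes listed in `truth$planted_gene_metabolite_links` track the
#' log-mean trajectory of their partner metabolite (in both treatments),
#' evaluated at the transcriptome stages; all other genes follow weak
#' independent trajectories. Values are log-normal and strictly positive.
#'
#' @param cfg a [synth_config()].
#' @param truth the truth object from [generate_metabolite_matrix()] run with
#'   the same configuration.
#' @return an [omics_matrix()] of `n_genes` x (2 x stages x replicates).
#' @export
generate_transcript_matrix <- function(cfg, truth) {
  validate_synth_config(cfg)
  if (is.null(truth$mu))
    stop("`truth` must come from generate_metabolite_matrix()")
  genes <- gene_ids(cfg)
  links <- truth$planted_gene_metabolite_links
  partner <- stats::setNames(links$metabolite_id, links$gene_id)
  latents <- module_latents(cfg)
  md <- sample_sheet(cfg$stages_trans, cfg$reps_trans)
  values <- matrix(NA_real_, nrow = length(genes), ncol = nrow(md),
                   dimnames = list(genes, md$sample_id))
  for (g in genes) {
    if (g %in% names(partner)) {
      p <- partner[[g]]
      mu_g <- mapply(function(cond, stage)
        truth$mu[[cond]][p, as.character(stage)], md$treatment, md$stage_daa)
    } else {
      tr <- cfg$background_loading *
        background_trajectory(cfg, latents, "traj_gene", g)
      mu_g <- tr[as.character(md$stage_daa)]
    }
    eps <- with_seed(substream_seed(cfg$seed, "noise_trans", g),
                     stats::rnorm(nrow(md), 0, cfg$noise_sd))
    values[g, ] <- exp(mu_g + eps)
  }
  omics_matrix(values, md)
}

#' Generate synthetic promoter sequences with planted motif instances
#'
#' One random sequence of `promoter_length` nt per gene with the configured
#' GC content. Each planted motif is instantiated (degenerate positions
#' resolved uniformly at random), placed at a uniform random position on a
#' random strand, and written over the background sequence — with probability
#' `motif_plant_rate_regulon` in regulon promoters and
#' `motif_plant_rate_background` elsewhere.
#'
#' @inheritParams generate_transcript_matrix
#' @return a named [Biostrings::DNAStringSet] (one promoter per gene).
#' @export
generate_promoters <- function(cfg, truth) {
  validate_synth_config(cfg)
  genes <- gene_ids(cfg)
  regulon <- truth$regulon_genes
  planted <- cfg$motif_library[
    match(cfg$planted_motif_ids, cfg$motif_library$motif_id), , drop = FALSE]
  gc <- cfg$gc_content
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  len <- cfg$promoter_length
  seqs <- character(length(genes))
  names(seqs) <- genes
  for (g in genes) {
    rate <- if (g %in% regulon) cfg$motif_plant_rate_regulon
            else cfg$motif_plant_rate_background
    seqs[[g]] <- with_seed(substream_seed(cfg$seed, "prom", g), {
      chars <- sample(names(base_prob), len, replace = TRUE, prob = base_prob)
      occupied <- logical(len)  # planted sites must not overwrite each other
      if (nrow(planted)) for (i in seq_len(nrow(planted))) {
        if (stats::runif(1) < rate) {
          site <- instantiate_motif(planted$consensus[i])
          if (sample(c(TRUE, FALSE), 1)) site <- revcomp_chr(site)
          w <- nchar(site)
          for (try in 1:100) {
            pos <- sample.int(len - w + 1L, 1)
            if (!any(occupied[pos:(pos + w - 1L)])) {
              chars[pos:(pos + w - 1L)] <- strsplit(site, "")[[1]]
              occupied[pos:(pos + w - 1L)] <- TRUE
              break
            }
          }
        }
      }
      paste(chars, collapse = "")
    })
  }
  Biostrings::DNAStringSet(seqs)
}

# Resolve a degenerate IUPAC consensus to one concrete instance.
instantiate_motif <- function(consensus) {
  paste(vapply(strsplit(toupper(consensus), "")[[1]], function(ch) {
    opts <- iupac_bases(ch)
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Generate a synthetic GO-slim term map
#'
#' Twelve broad terms; one ("terpenoid metabolic process" analogue) is
#' preferentially assigned to regulon genes so that set enrichment has a
#' planted positive. Assignments are deterministic given the seed.
#'
#' @inheritParams generate_transcript_matrix
#' @return named list, term -> character vector of gene IDs.
#' @export
generate_go_map <- function(cfg, truth) {
  genes <- gene_ids(cfg)
  terms <- c("terpenoid_process", "phenylpropanoid_process", "lipid_process",
             "carbohydrate_process", "transport", "signal_transduction",
             "response_to_stress", "response_to_abiotic_stimulus",
             "transcription_regulation", "protein_modification",
             "photosynthesis", "cell_wall_organization")
  with_seed(substream_seed(cfg$seed, "go"), {
    out <- list()
    for (tm in terms) {
      if (tm == "terpenoid_process") {
        keep <- union(
          truth$regulon_genes[stats::runif(length(truth$regulon_genes)) < 0.6],
          genes[stats::runif(length(genes)) < 0.02])
      } else {
        keep <- genes[stats::runif(length(genes)) < stats::runif(1, 0.02, 0.1)]
      }
      out[[tm]] <- sort(keep)
    }
    out
  })
}

#' Generate a synthetic pathway annotation map
#'
#' Linked genes are terpenoid-pathway structural genes; a random subset of
#' the remaining genes is spread over the other pathways and the rest stays
#' unannotated.
#'
#' @inheritParams generate_transcript_matrix
#' @return named character vector, gene ID -> pathway label.
#' @export
generate_pathway_map <- function(cfg, truth) {
  genes <- gene_ids(cfg)
  linked <- truth$planted_gene_metabolite_links$gene_id
  with_seed(substream_seed(cfg$seed, "pathway"), {
    others <- setdiff(genes, linked)
    annotated <- others[stats::runif(length(others)) < 0.3]
    pw <- sample(c("phenylpropanoid", "flavonoid", "carotenoid", "fatty_acid"),
                 length(annotated), replace = TRUE)
    stats::setNames(c(rep("terpenoid", length(linked)), pw),
                    c(linked, annotated))
  })
}

#' Generate a complete synthetic multi-omics dataset
#'
#' Runs all generators under one configuration and returns the matrices,
#' promoters, motif library, annotation maps, DE flags and the ground-truth
#' object together.
#'
#' @param cfg a [synth_config()].
#' @return a `synthetic_dataset` list with elements `metabolites`,
#'   `transcripts`, `promoters`, `motif_library`, `go_map`, `pathway_map`,
#'   `de_flags`, `truth`, `config`.
#' @export
generate_dataset <- function(cfg) {
  gm <- generate_metabolite_matrix(cfg)
  trans <- generate_transcript_matrix(cfg, gm$truth)
  prom <- generate_promoters(cfg, gm$truth)
  structure(list(
    metabolites = gm$matrix,
    transcripts = trans,
    promoters = prom,
    motif_library = cfg$motif_library,
    go_map = generate_go_map(cfg, gm$truth),
    pathway_map = generate_pathway_map(cfg, gm$truth),
    de_flags = gm$truth$de_flags,
    truth = gm$truth,
    config = cfg), class = "synthetic_dataset")
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Matrices and metadata as TSV, promoters as FASTA, the motif library as
#' TSV, annotation maps as TSV, and the truth object as JSON.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_omics_tsv(dataset$metabolites, p("metabolites.tsv"),
                  p("metabolite_samples.tsv"))
  write_omics_tsv(dataset$transcripts, p("transcripts.tsv"),
                  p("transcript_samples.tsv"))
  Biostrings::writeXStringSet(dataset$promoters, p("promoters.fa"))
  utils::write.table(dataset$motif_library, p("motifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  go_df <- data.frame(
    term = rep(names(dataset$go_map),
               vapply(dataset$go_map, length, integer(1))),
    gene_id = unlist(dataset$go_map, use.names = FALSE))
  utils::write.table(go_df, p("go_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pw_df <- data.frame(gene_id = names(dataset$pathway_map),
                      pathway = unname(dataset$pathway_map))
  utils::write.table(pw_df, p("pathway_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(dataset$de_flags, p("de_flags.txt"))
  truth <- dataset$truth
  truth$mu <- lapply(truth$mu, function(m)
    list(stages = colnames(m), features = rownames(m), values = m))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(list.files(dir, full.names = TRUE))
}
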