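#' Configuration for the synthetic bulk RNA-seq generator
#'
#' Defines the study conditions the generator emulates: 50 donors (18 female,
#' 32 male), negative-binomial gene counts with per-sample sequencing depths
#' in the published 40-110 million read range, a handful of mitochondrial
#' genes expressed far above the rest, and planted co-expression modules
#' driven by a shared per-module latent factor. One module supplies the seed
#' gene list; within-module pairs supply the gold-standard network.
#'
#' @param n_genes total number of genes (default 2000).
#' @param n_samples number of samples (default 50).
#' @param n_female number of female samples (default 18; the rest are male).
#' @param module_specs list of `list(size =, loading_scale =)` planted
#'   modules. `loading_scale` is the log-scale loading b on the module's
#'   latent factor; 0 = no co-expression.
#' @param seed_fraction fraction of the first module designated as seed
#'   genes (default 0.3).
#' @param nb_dispersion negative-binomial size parameter (variance =
#'   mu + mu^2 / dispersion), shared across genes (default 40, i.e. about
#'   16% residual coefficient of variation once the module factor is
#'   accounted for separately).
#' @param depth_range min/max reads per sample (default 40e6-110e6).
#' @param length_range min/max gene length in bp, drawn log-uniformly
#'   (default 300-20000).
#' @param mito_genes number of mitochondrial genes (default 13), placed on
#'   chromosome "MT".
#' @param mito_multiplier expression multiplier for mitochondrial genes
#'   (default 17, putting roughly 10% of reads on chrMT in expectation).
#' @param n_ref_transcripts reference transcripts in the toy transcript
#'   fixture (default 6).
#' @param ci_zero_fraction fraction of per-transcript-per-sample expression
#'   confidence intervals whose lower bound is 0 in the fixture (default 0.3).
#' @param rng_seed integer seed; all randomness funnels through it, with
#'   per-component sub-streams derived by fixed offsets.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_samples = 50,
                              n_female = 18,
                              module_specs = list(list(size = 100,
                                                       loading_scale = 1)),
                              seed_fraction = 0.3,
                              nb_dispersion = 40,
                              depth_range = c(40e6, 110e6),
                              length_range = c(300, 20000),
                              mito_genes = 13,
                              mito_multiplier = 17,
                              n_ref_transcripts = 6,
                              ci_zero_fraction = 0.3,
                              rng_seed = 1L) {
  sizes <- vapply(module_specs, function(m) m$size, numeric(1))
  if (sum(sizes) + mito_genes > n_genes) {
    stop("module sizes plus mitochondrial genes exceed n_genes")
  }
  stopifnot(n_female <= n_samples, n_female >= 0,
            seed_fraction >= 0, seed_fraction <= 1,
            nb_dispersion > 0,
            depth_range[1] <= depth_range[2], depth_range[1] > 0,
            length_range[1] <= length_range[2], length_range[1] > 0,
            mito_multiplier > 0)
  structure(
    list(n_genes = n_genes, n_samples = n_samples, n_female = n_female,
         module_specs = module_specs, seed_fraction = seed_fraction,
         nb_dispersion = nb_dispersion, depth_range = depth_range,
         length_range = length_range, mito_genes = mito_genes,
         mito_multiplier = mito_multiplier,
         n_ref_transcripts = n_ref_transcripts,
         ci_zero_fraction = ci_zero_fraction,
         rng_seed = as.integer(rng_seed)),
    class = "sim_config"
  )
}

# deterministic per-component sub-stream (keeps derived seeds < 2^31)
sub_seed <- function(config, offset) {
  (config$rng_seed + 7919L * offset) %% .Machine$integer.max
}

#' Generate a synthetic dataset with planted co-expression modules
#'
#' Gene g in module m has negative-binomial counts with mean
#' `mu_gs = depth_s * w_gs / sum_g(w_gs)` where
#' `w_gs = base_g * exp(b_g * z_m(s))`, `z_m(s)` a standard-normal latent
#' factor shared by the module's genes within sample s, and `b_g` the
#' module's loading scale. Background genes have `b_g = 0`; mitochondrial
#' genes have their baseline multiplied. Per-sample column sums therefore
#' match the drawn depths in expectation. The same `rng_seed` reproduces the
#' dataset byte-for-byte.
#'
#' @param config a [simulation_config()].
#' @param transcripts also attach the toy transcript fixture from
#'   [generate_transcript_fixture()] (default TRUE).
#' @return a `synthetic_dataset` list: `counts` (integer matrix),
#'   `annotation` (data.frame gene_id/length_bp/chromosome), `sample_sex`
#'   (named "F"/"M" vector), `true_modules` (named integer vector, NA =
#'   background), `seed_genes`, `depths`, `config`, and (optionally)
#'   `fixture` from the transcript generator.
#' @export
simulate_dataset <- function(config = simulation_config(),
                             transcripts = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n_g <- config$n_genes
  n_s <- config$n_samples
  gene_ids <- sprintf("gene%05d", seq_len(n_g))
  sample_ids <- sprintf("S%02d", seq_len(n_s))
  sex <- stats::setNames(
    c(rep("F", config$n_female), rep("M", n_s - config$n_female)),
    sample_ids)

  # --- annotation: lengths log-uniform, chromosomes arbitrary, MT last ----
  set.seed(sub_seed(config, 1L))
  len <- round(exp(stats::runif(n_g, log(config$length_range[1]),
                                log(config$length_range[2]))))
  chrom <- sample(paste0("chr", c(1:22, "X")), n_g, replace = TRUE)
  mito_idx <- if (config$mito_genes > 0) {
    seq.int(n_g - config$mito_genes + 1L, n_g)
  } else integer(0)
  chrom[mito_idx] <- "MT"
  annotation <- data.frame(gene_id = gene_ids, length_bp = len,
                           chromosome = chrom, stringsAsFactors = FALSE)

  # --- module membership: consecutive blocks from the top, MT excluded ----
  sizes <- vapply(config$module_specs, function(m) m$size, numeric(1))
  loadings <- vapply(config$module_specs, function(m) m$loading_scale,
                     numeric(1))
  modules <- rep(NA_integer_, n_g)
  b <- numeric(n_g)
  at <- 0L
  for (m in seq_along(sizes)) {
    idx <- seq.int(at + 1L, at + sizes[m])
    modules[idx] <- m
    b[idx] <- loadings[m]
    at <- at + sizes[m]
  }
  names(modules) <- gene_ids

  # --- expression baselines and depths -----------------------------------
  set.seed(sub_seed(config, 2L))
  base <- stats::rlnorm(n_g, meanlog = 0, sdlog = 1.5)
  base[mito_idx] <- base[mito_idx] * config$mito_multiplier
  depths <- round(stats::runif(n_s, config$depth_range[1],
                               config$depth_range[2]))

  # --- latent factors and NB draws ---------------------------------------
  set.seed(sub_seed(config, 3L))
  n_mod <- length(sizes)
  z <- if (n_mod > 0) {
    matrix(stats::rnorm(n_mod * n_s), n_mod, n_s)
  } else matrix(0, 0, n_s)
  w <- matrix(base, n_g, n_s)
  if (n_mod > 0) {
    in_mod <- !is.na(modules)
    w[in_mod, ] <- w[in_mod, ] * exp(b[in_mod] * z[modules[in_mod], ,
                                                   drop = FALSE])
  }
  mu <- sweep(w, 2, depths / colSums(w), "*")
  counts <- matrix(
    stats::rnbinom(n_g * n_s, mu = mu, size = config$nb_dispersion),
    n_g, n_s, dimnames = list(gene_ids, sample_ids))

  # --- seed genes: random draw from module 1 -----------------------------
  seed_genes <- character(0)
  if (n_mod > 0 && config$seed_fraction > 0) {
    m1 <- gene_ids[which(modules == 1L)]
    set.seed(sub_seed(config, 4L))
    seed_genes <- sort(sample(m1, ceiling(config$seed_fraction * length(m1))))
  }

  out <- structure(
    list(counts = counts, annotation = annotation, sample_sex = sex,
         true_modules = modules, seed_genes = seed_genes,
         depths = stats::setNames(depths, sample_ids), config = config),
    class = "synthetic_dataset"
  )
  if (transcripts) out$fixture <- generate_transcript_fixture(config)
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d genes x %d samples (%dF/%dM), %d module(s), %d seed genes\n",
    nrow(x$counts), ncol(x$counts), sum(x$sample_sex == "F"),
    sum(x$sample_sex == "M"),
    length(unique(stats::na.omit(x$true_modules))), length(x$seed_genes)))
  invisible(x)
}

#' All within-module gene pairs of a synthetic dataset
#'
#' @param dataset a `synthetic_dataset`.
#' @return data.frame `gene_i`, `gene_j`, `module` (gene_i < gene_j); every
#'   unordered pair of genes planted in the same module.
#' @export
within_module_pairs <- function(dataset) {
  mods <- dataset$true_modules
  out <- lapply(sort(unique(stats::na.omit(mods))), function(m) {
    g <- sort(names(mods)[which(mods == m)])
    if (length(g) < 2) return(NULL)
    idx <- utils::combn(g, 2)
    data.frame(gene_i = idx[1, ], gene_j = idx[2, ], module = m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample a gold-standard edge set from the planted modules
#'
#' Stands in for an external interaction database: a reproducible random
#' sample of the within-module pairs. Edges never connect two different
#' modules, by construction.
#'
#' @param dataset a `synthetic_dataset`.
#' @param fraction fraction of within-module pairs to keep, in (0, 1\].
#' @return data.frame `gene_i`, `gene_j` (gene_i < gene_j).
#' @export
make_gold_standard <- function(dataset, fraction = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  pairs <- within_module_pairs(dataset)
  if (is.null(pairs)) stop("dataset has no planted module pairs")
  n_keep <- round(fraction * nrow(pairs))
  set.seed(sub_seed(dataset$config, 5L))
  keep <- sort(sample.int(nrow(pairs), n_keep))
  out <- pairs[keep, c("gene_i", "gene_j"), drop = FALSE]
  rownames(out) <- NULL
  out
}
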