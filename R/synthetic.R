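# Synthetic proteomic data with planted structure. Every downstream stage
# (QC, differential expression, network inference, community detection,
# enrichment, topology statistics) has a ground-truth recovery test built
# on these generators.

#' Configuration for the synthetic-data generator
#'
#' Defines a nested latent-factor model emulating a tumor proteomics study:
#' proteins are split into modules, each module into submodules, and a
#' protein's abundance in sample s is
#' \deqn{x_{ps} = \lambda f_m(s) + (\lambda/2) g_{mk}(s) + \epsilon_{ps}}
#' with independent standard-normal factors f (per module) and g (per
#' submodule) and noise sd `noise_sd`. The submodule loading is fixed at
#' half the module loading so submodules are detectable only after a first
#' level of community splitting, mirroring a two-level hierarchy.
#' Differentially abundant proteins get `de_effect` added (sign per
#' protein) in tumor samples; entries are then masked missing completely
#' at random at rate `missing_rate`; chromosomes are assigned uniformly at
#' random (so the expected cis-edge fraction is 1/`n_chromosomes`) or
#' aligned with modules.
#'
#' @param n_proteins,n_tumor,n_healthy matrix dimensions (defaults emulate
#'   a ~100-tumor, 3-healthy study at desk scale).
#' @param n_modules,submodules_per_module planted hierarchy.
#' @param module_loading latent-factor loading lambda (unitless); the
#'   within-module correlation is lambda^2 / (lambda^2 + noise_sd^2) plus
#'   the submodule contribution.
#' @param noise_sd residual standard deviation (> 0).
#' @param de_fraction fraction of proteins with a planted tumor shift.
#' @param de_effect size of the planted shift (log2 units).
#' @param de_pattern `"random"`: each affected protein gets an independent
#'   random sign; `"module"`: all proteins of a module share one sign (the
#'   regime that makes expression assortativity approach 1).
#' @param missing_rate fraction of entries masked missing at random.
#' @param n_chromosomes number of chromosome labels.
#' @param chromosome_pattern `"random"`: uniform assignment independent of
#'   modules; `"module"`: each module sits on one chromosome (the regime
#'   with cis fraction near 1).
#' @param seed integer RNG seed; same config + seed gives bit-identical
#'   output.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 1000,
                             n_tumor = 100,
                             n_healthy = 3,
                             n_modules = 4,
                             submodules_per_module = 3,
                             module_loading = 2,
                             noise_sd = 1,
                             de_fraction = 0.2,
                             de_effect = 2,
                             de_pattern = c("random", "module"),
                             missing_rate = 0.05,
                             n_chromosomes = 23,
                             chromosome_pattern = c("random", "module"),
                             seed = 1) {
  de_pattern <- match.arg(de_pattern)
  chromosome_pattern <- match.arg(chromosome_pattern)
  for (f in c("n_proteins", "n_tumor", "n_healthy", "n_modules",
              "submodules_per_module", "n_chromosomes"))
    stop_if_not_count(get(f), f)
  for (f in c("de_fraction", "missing_rate"))
    stop_if_not_fraction(get(f), f)
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("'noise_sd' must be > 0")
  if (!is.numeric(module_loading) || module_loading < 0)
    stop("'module_loading' must be >= 0")
  if (n_modules * submodules_per_module > n_proteins)
    stop("'n_modules' x 'submodules_per_module' exceeds 'n_proteins'")
  cfg <- list(n_proteins = n_proteins, n_tumor = n_tumor,
              n_healthy = n_healthy, n_modules = n_modules,
              submodules_per_module = submodules_per_module,
              module_loading = module_loading, noise_sd = noise_sd,
              de_fraction = de_fraction, de_effect = de_effect,
              de_pattern = de_pattern, missing_rate = missing_rate,
              n_chromosomes = n_chromosomes,
              chromosome_pattern = chromosome_pattern, seed = seed)
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic proteomic dataset with planted truth
#'
#' @param config a [synthetic_config()].
#' @return list with elements
#'   \describe{
#'     \item{matrix}{an [expression_matrix()] (proteins x samples, `NA`
#'       for masked entries, tumor/healthy groups).}
#'     \item{truth}{data.frame with columns `protein`, `module`,
#'       `submodule` (label `"M<m>.<k>"`), `de_sign` (+1/-1/0) and
#'       `chromosome` — the planted assignments.}
#'   }
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  with_seed(config$seed, {
    np <- config$n_proteins
    ns <- config$n_tumor + config$n_healthy
    proteins <- sprintf("P%04d", seq_len(np))
    samples <- c(sprintf("T%03d", seq_len(config$n_tumor)),
                 sprintf("H%03d", seq_len(config$n_healthy)))
    group <- setNames(rep(c("tumor", "healthy"),
                          c(config$n_tumor, config$n_healthy)), samples)

    # even assignment of proteins to modules, then submodules within module
    module <- rep(seq_len(config$n_modules), length.out = np)
    module <- sort(module)
    submodule <- integer(np)
    for (m in seq_len(config$n_modules)) {
      in_m <- which(module == m)
      submodule[in_m] <- sort(rep(seq_len(config$submodules_per_module),
                                  length.out = length(in_m)))
    }

    lambda <- config$module_loading
    f <- matrix(rnorm(config$n_modules * ns), config$n_modules, ns)
    eps <- matrix(rnorm(np * ns, sd = config$noise_sd), np, ns)
    vals <- lambda * f[module, , drop = FALSE] + eps
    if (config$submodules_per_module > 1) {
      # nested level at half the loading: only present when the planted
      # hierarchy actually has a second level
      g <- array(rnorm(config$n_modules * config$submodules_per_module * ns),
                 dim = c(config$n_modules, config$submodules_per_module, ns))
      vals <- vals +
        (lambda / 2) * matrix(g[cbind(rep(module, ns), rep(submodule, ns),
                                      rep(seq_len(ns), each = np))], np, ns)
    }

    # planted differential abundance in tumor samples
    n_de <- round(config$de_fraction * np)
    de_idx <- sample.int(np, n_de)
    de_sign <- integer(np)
    if (n_de > 0) {
      if (config$de_pattern == "module") {
        module_sign <- sample(c(-1L, 1L), config$n_modules, replace = TRUE)
        de_sign[de_idx] <- module_sign[module[de_idx]]
      } else {
        de_sign[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
      }
      tumor_cols <- seq_len(config$n_tumor)
      vals[de_idx, tumor_cols] <- vals[de_idx, tumor_cols] +
        de_sign[de_idx] * config$de_effect
    }

    # chromosomes: independent of modules, or module-aligned
    chrom_labels <- as.character(seq_len(config$n_chromosomes))
    chromosome <- if (config$chromosome_pattern == "module") {
      chrom_labels[((module - 1) %% config$n_chromosomes) + 1]
    } else {
      sample(chrom_labels, np, replace = TRUE)
    }

    # missing completely at random, applied after signal generation
    if (config$missing_rate > 0) {
      mask <- runif(np * ns) < config$missing_rate
      vals[matrix(mask, np, ns)] <- NA_real_
    }

    dimnames(vals) <- list(proteins, samples)
    truth <- data.frame(protein = proteins, module = module,
                        submodule = sprintf("M%d.%d", module, submodule),
                        de_sign = de_sign, chromosome = chromosome,
                        stringsAsFactors = FALSE)
    list(matrix = expression_matrix(vals, group), truth = truth)
  })
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Writes `matrix.tsv` (the abundance matrix), `metadata.tsv` (sample id,
#' group, flagged), `chromosomes.tsv` (gene, chromosome) and `truth.tsv`
#' (the planted assignments).
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(dataset$matrix, file.path(dir, "matrix.tsv"))
  md <- data.frame(sample_id = colnames(dataset$matrix$values),
                   group = unname(dataset$matrix$group),
                   flagged = FALSE)
  write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dataset$truth[, c("protein", "chromosome")],
              file.path(dir, "chromosomes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
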