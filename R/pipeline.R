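# Pipeline driver tying the proxies together: a validated configuration, one
# run_stage() entry point per stage, CSV/Newick I/O with metadata comment
# lines, and a machine-readable run log. A thin command-line wrapper lives at
# inst/cli/paleotroph.

pipeline_stages <- c("simulate", "mass", "claws", "jaws", "fea",
                     "signal", "hsd", "ordinate", "synthesize")

config_defaults <- function() {
  list(
    seed = 1L,
    n_permutations = 1000L,
    lambda = "optimize",
    interval_start_n = 10L,
    interval_step = 5L,
    interval_max_n = 100L,
    interval_threshold = 0.99,
    likely_threshold = 0.10,
    delta_fraction = 0.65,
    n_extant = 60L,
    n_fossil = 3L,
    input_dir = ".",
    output_dir = "."
  )
}

#' Build and validate a pipeline configuration
#'
#' Fills defaults (seed, permutation count, lambda mode, interval settings,
#' likely-threshold, I/O directories) and rejects unknown keys so that typos
#' fail loudly rather than silently running with defaults.
#'
#' @param ... Configuration entries overriding the defaults.
#' @return Named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- config_defaults()
  user <- list(...)
  if (length(user) > 0L && is.null(names(user))) stop("config entries must be named", call. = FALSE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(user)] <- user
  structure(cfg, class = "pipeline_config")
}

# CSV with "#"-prefixed metadata comment lines (units, seed)
write_stage_csv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_stage_csv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, " lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_run_log <- function(config, stage, inputs, outputs) {
  log <- list(
    stage = stage,
    seed = config$seed,
    config = unclass(config),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("paleotroph")),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = outputs
  )
  path <- file.path(config$output_dir, paste0("run_log_", stage, ".json"))
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write synthetic inputs: tree, traits, masses, jaw
#' measurements, strain elements), `mass` (Youden cut-points from species
#' masses), `claws` (claw table from landmark CSV), `jaws` (indices from
#' measurement CSV), `fea` (MWAM + interval compositions + ilr coordinates),
#' `signal` (K_mult on traits x tree), `hsd` (phylogenetic HSD), `ordinate`
#' (PCA + FDA with independent fossil projection), `synthesize` (combine
#' per-proxy posteriors into likely/unlikely/agreed sets). Identical config
#' and seed give identical outputs; each stage writes a JSON run log with
#' input hashes and the seed.
#'
#' @param config A [pipeline_config()].
#' @param stage Stage name.
#' @return Invisible character vector of files written.
#' @export
run_stage <- function(config, stage) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!stage %in% pipeline_stages) {
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(pipeline_stages, collapse = ", "), call. = FALSE)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(stage,
    simulate = stage_simulate(config),
    mass = stage_mass(config),
    claws = stage_claws(config),
    jaws = stage_jaws(config),
    fea = stage_fea(config),
    signal = stage_signal(config),
    hsd = stage_hsd(config),
    ordinate = stage_ordinate(config),
    synthesize = stage_synthesize(config)
  )
  write_run_log(config, stage, inputs = attr(out, "inputs") %||% character(0),
                outputs = as.character(out))
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

in_path <- function(config, name) file.path(config$input_dir, name)
out_path <- function(config, name) file.path(config$output_dir, name)

stage_simulate <- function(config) {
  set.seed(config$seed)
  n <- config$n_extant
  tree <- ape::rcoal(n, tip.label = paste0("sp", seq_len(n)))
  tree$edge.length <- tree$edge.length * (94 / max(ape::node.depth.edgelength(tree)))
  diets <- c("Invertivore", "Piscivore", "Generalist", "Folivore")
  groups <- stats::setNames(rep(diets, length.out = n), tree$tip.label)
  traits <- simulate_bm_traits(tree, p = 4, seed = config$seed)
  shift <- stats::model.matrix(~ 0 + groups)[, paste0("groups", diets)] %*%
    matrix(stats::rnorm(length(diets) * 4, 0, 2), length(diets))
  traits <- traits + shift
  masses <- simulate_mass_data(seed = config$seed)
  fossil_names <- paste0("fossil", seq_len(config$n_fossil))
  fossil_traits <- traits[seq_len(config$n_fossil), , drop = FALSE] +
    matrix(stats::rnorm(config$n_fossil * 4, 0, 0.5), config$n_fossil)
  rownames(fossil_traits) <- fossil_names
  fields <- simulate_strain_fields(
    stats::setNames(stats::runif(n, 60, 430), tree$tip.label),
    n_elements = 150, seed = config$seed)
  elements <- do.call(rbind, lapply(names(fields), function(m) {
    data.frame(model = m, element_id = seq_len(nrow(fields[[m]])),
               area = fields[[m]]$area, strain_microstrain = fields[[m]]$strain)
  }))
  meta <- paste0("seed = ", config$seed)
  files <- c(
    tree = out_path(config, "tree.nwk"),
    traits = out_path(config, "traits.csv"),
    masses = out_path(config, "masses.csv"),
    elements = out_path(config, "strain_elements.csv")
  )
  writeLines(write_newick(tree), files[["tree"]])
  write_stage_csv(
    data.frame(taxon = c(rownames(traits), fossil_names),
               rbind(traits, fossil_traits),
               group = c(groups, rep(NA, config$n_fossil)),
               fossil = c(rep(FALSE, n), rep(TRUE, config$n_fossil))),
    files[["traits"]], c("synthetic trait table; traits unitless", meta))
  write_stage_csv(masses, files[["masses"]],
                  c("log10_mass in log10 grams", meta))
  write_stage_csv(elements, files[["elements"]],
                  c("area in model units^2, strain in microstrain", meta))
  files
}

stage_mass <- function(config) {
  path <- in_path(config, "masses.csv")
  masses <- require_columns(read_stage_csv(path), c("diet", "log10_mass"), path)
  cuts <- mass_cutpoints(masses$log10_mass, masses$diet)
  out <- out_path(config, "mass_cutpoints.csv")
  write_stage_csv(cuts, out, c("threshold_g in grams; threshold_log10 in log10 grams",
                               paste0("seed = ", config$seed)))
  structure(out, inputs = path)
}

stage_claws <- function(config) {
  path <- in_path(config, "claw_landmarks.csv")
  lm <- require_columns(read_stage_csv(path),
                        c("specimen", "digit", "landmark", "x", "y"), path)
  specs <- split(lm, lm$specimen)
  tab <- do.call(rbind, lapply(names(specs), function(sp) {
    arcs <- lapply(split(specs[[sp]], specs[[sp]]$digit), function(d) {
      as.matrix(d[order(d$landmark), c("x", "y")])
    })
    cbind(specimen = sp, tm_record(arcs))
  }))
  out <- out_path(config, "tm_table.csv")
  write_stage_csv(tab, out, c("curvatures in degrees; ratios dimensionless",
                              paste0("seed = ", config$seed)))
  structure(out, inputs = path)
}

stage_jaws <- function(config) {
  path <- in_path(config, "jaw_measurements.csv")
  jm <- require_columns(read_stage_csv(path), "taxon", path)
  tab <- do.call(rbind, lapply(seq_len(nrow(jm)), function(i) {
    cbind(taxon = jm$taxon[i], jaw_indices(jm[i, ]))
  }))
  out <- out_path(config, "jaw_indices.csv")
  write_stage_csv(tab, out, c("all indices dimensionless ratios",
                              paste0("seed = ", config$seed)))
  structure(out, inputs = path)
}

stage_fea <- function(config) {
  path <- in_path(config, "strain_elements.csv")
  el <- require_columns(read_stage_csv(path),
                        c("model", "area", "strain_microstrain"), path)
  fields <- lapply(split(el, el$model), function(d) {
    data.frame(area = d$area, strain = d$strain_microstrain)
  })
  mw <- data.frame(model = names(fields),
                   mwam_microstrain = vapply(fields, mwam, numeric(1)))
  conv <- converge_intervals(fields, start_n = config$interval_start_n,
                             step = config$interval_step,
                             max_n = config$interval_max_n,
                             criterion_threshold = config$interval_threshold,
                             delta_fraction = config$delta_fraction)
  n_int <- if (conv$converged) conv$n else config$interval_max_n
  comp <- interval_composition(fields, interval_spec(fields, n_int))
  coords <- ilr(impute_zeros(comp, delta_fraction = config$delta_fraction))
  files <- c(mwam = out_path(config, "mwam.csv"),
             comp = out_path(config, "interval_composition.csv"),
             ilr = out_path(config, "ilr_coordinates.csv"))
  meta <- paste0("seed = ", config$seed)
  write_stage_csv(mw, files[["mwam"]], c("mwam in microstrain", meta))
  write_stage_csv(data.frame(model = rownames(comp), comp, check.names = FALSE),
                  files[["comp"]],
                  c(paste0("percent model area per strain interval; n_intervals = ",
                           n_int, "; converged = ", conv$converged), meta))
  write_stage_csv(data.frame(model = rownames(coords), coords, check.names = FALSE),
                  files[["ilr"]], c("ilr coordinates (dimensionless)", meta))
  structure(files, inputs = path)
}

read_trait_inputs <- function(config) {
  tpath <- in_path(config, "traits.csv")
  trpath <- in_path(config, "tree.nwk")
  traits <- require_columns(read_stage_csv(tpath), c("taxon", "fossil"), tpath)
  if (!file.exists(trpath)) stop("missing input file: ", trpath, call. = FALSE)
  tree <- read_newick(paste(readLines(trpath), collapse = ""))
  extant <- traits[!traits$fossil, ]
  mismatch <- setdiff(extant$taxon, tree$tip.label)
  if (length(mismatch) > 0L) {
    stop("taxa absent from tree: ", paste(mismatch, collapse = ", "), call. = FALSE)
  }
  vars <- setdiff(names(traits), c("taxon", "group", "fossil"))
  list(traits = traits, tree = tree, vars = vars,
       extant = extant, inputs = c(tpath, trpath))
}

stage_signal <- function(config) {
  inp <- read_trait_inputs(config)
  C <- bm_covariance(prune_to(inp$tree, inp$extant$taxon))
  Y <- as.matrix(inp$extant[, inp$vars])
  rownames(Y) <- inp$extant$taxon
  sig <- k_mult(Y, C, n_perm = config$n_permutations, seed = config$seed)
  out <- out_path(config, "phylo_signal.json")
  jsonlite::write_json(list(k_mult = sig$statistic, p_value = sig$p_value,
                            n_permutations = sig$n_permutations,
                            seed = config$seed),
                       out, auto_unbox = TRUE, digits = NA)
  structure(out, inputs = inp$inputs)
}

stage_hsd <- function(config) {
  inp <- read_trait_inputs(config)
  ext <- inp$extant[!is.na(inp$extant$group), ]
  C <- bm_covariance(prune_to(inp$tree, ext$taxon))
  Y <- as.matrix(ext[, inp$vars])
  rownames(Y) <- ext$taxon
  res <- phylogenetic_hsd(Y, ext$group, C, n_perm = config$n_permutations,
                          seed = config$seed)
  files <- c(dist = out_path(config, "hsd_distances.csv"),
             p = out_path(config, "hsd_pvalues.csv"))
  meta <- paste0("seed = ", config$seed)
  write_stage_csv(data.frame(group = rownames(res$distances), res$distances,
                             check.names = FALSE),
                  files[["dist"]], c("Euclidean distances between group GLS means", meta))
  write_stage_csv(data.frame(group = rownames(res$p_values), res$p_values,
                             check.names = FALSE),
                  files[["p"]], c(paste0("permutation p-values, n_perm = ",
                                         res$n_permutations), meta))
  structure(files, inputs = inp$inputs)
}

stage_ordinate <- function(config) {
  inp <- read_trait_inputs(config)
  ext <- inp$extant[!is.na(inp$extant$group), ]
  fos <- inp$traits[inp$traits$fossil, ]
  X <- as.matrix(ext[, inp$vars]); rownames(X) <- ext$taxon
  Xf <- as.matrix(fos[, inp$vars]); rownames(Xf) <- fos$taxon
  pca <- pca_correlation(X)
  fda <- fda_fit(X, ext$group)
  post <- discriminant_predict(fda, Xf)
  files <- c(scores = out_path(config, "pca_scores.csv"),
             fossil_scores = out_path(config, "pca_fossil_scores.csv"),
             posteriors = out_path(config, "fda_fossil_posteriors.csv"))
  meta <- paste0("seed = ", config$seed)
  write_stage_csv(data.frame(taxon = rownames(pca$scores), pca$scores,
                             check.names = FALSE),
                  files[["scores"]], c("correlation-matrix PCA scores (dimensionless)", meta))
  write_stage_csv(data.frame(taxon = rownames(Xf), project(pca, Xf),
                             check.names = FALSE),
                  files[["fossil_scores"]],
                  c("fossil rows projected independently of the fitted rotation", meta))
  write_stage_csv(data.frame(taxon = rownames(Xf), post,
                             predicted = attr(post, "predicted"),
                             check.names = FALSE),
                  files[["posteriors"]], c("FDA class posterior probabilities", meta))
  structure(files, inputs = inp$inputs)
}

stage_synthesize <- function(config) {
  path <- in_path(config, "fda_fossil_posteriors.csv")
  post <- require_columns(read_stage_csv(path), "taxon", path)
  cats <- setdiff(names(post), c("taxon", "predicted"))
  out <- out_path(config, "evidence_summary.json")
  summaries <- lapply(seq_len(nrow(post)), function(i) {
    p <- stats::setNames(as.numeric(post[i, cats]), cats)
    evidence_summary(list(ordination = p),
                     likely_threshold = config$likely_threshold)
  })
  names(summaries) <- post$taxon
  jsonlite::write_json(list(seed = config$seed,
                            likely_threshold = config$likely_threshold,
                            fossils = summaries),
                       out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(out, inputs = path)
}
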