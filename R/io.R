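GENO_CODES <- list(two = c(A = 1L, H = 2L), f2 = c(A = 1L, H = 2L, B = 3L))
MISSING_CODES <- c("-", "NA", "", "N")

#' Read a cross dataset from CSV files
#'
#' Genotype CSV: first column individual id, remaining columns one marker
#' each (codes `A`/`H` for backcross/DH/RIL mapped to classes 1/2,
#' `A`/`H`/`B` for F2; `-`, `NA` or empty = missing).  Phenotype CSV:
#' columns `id`, `pheno`, optional `trials`.  Markers are aligned to the map
#' and individuals between genotype and phenotype tables.
#'
#' @param map_csv,genotype_csv,phenotype_csv File paths.
#' @param design Cross design.
#' @param family Trait family (used to validate the phenotype column).
#' @param trials Default binomial denominator when the phenotype table has
#'   no `trials` column.
#' @return An object of class `"qtl_cross"`: list with `map`, `geno`
#'   (integer class matrix), `pheno`, `trials`, `ids`, `design`.
#' @export
read_cross <- function(map_csv, genotype_csv, phenotype_csv,
                       design = c("backcross", "dh", "ril", "f2"),
                       family = c("binomial", "poisson", "gaussian"),
                       trials = 1) {
  design <- match.arg(design)
  family <- match.arg(family)
  map <- read_map_csv(map_csv)
  gdf <- utils::read.csv(genotype_csv, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (ncol(gdf) < 2) stop("genotype CSV must have an id column plus markers")
  ids <- gdf[[1]]
  if (anyDuplicated(ids)) stop("duplicate individual id(s) in genotype CSV: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  gmark <- names(gdf)[-1]
  unknown <- setdiff(gmark, map$marker)
  if (length(unknown)) stop("genotype column(s) absent from map: ",
                            paste(unknown, collapse = ", "))
  absent <- setdiff(map$marker, gmark)
  if (length(absent)) stop("map marker(s) absent from genotype CSV: ",
                           paste(absent, collapse = ", "))
  codes <- if (design == "f2") GENO_CODES$f2 else GENO_CODES$two
  geno <- matrix(NA_integer_, nrow(gdf), nrow(map),
                 dimnames = list(ids, map$marker))
  for (mk in map$marker) {
    v <- trimws(gdf[[mk]])
    miss <- v %in% MISSING_CODES | is.na(v)
    bad <- !miss & !(v %in% names(codes))
    if (any(bad))
      stop("invalid genotype code '", v[which(bad)[1]], "' for marker ", mk,
           ", individual ", ids[which(bad)[1]])
    geno[!miss, mk] <- codes[v[!miss]]
  }
  pdf <- utils::read.csv(phenotype_csv, stringsAsFactors = FALSE)
  if (!all(c("id", "pheno") %in% names(pdf)))
    stop("phenotype CSV must have columns id, pheno")
  if (anyDuplicated(pdf$id)) stop("duplicate individual id(s) in phenotype CSV")
  m <- match(ids, as.character(pdf$id))
  if (anyNA(m)) stop("individual(s) missing from phenotype CSV: ",
                     paste(ids[is.na(m)][1:min(5, sum(is.na(m)))], collapse = ", "))
  y <- pdf$pheno[m]
  tr <- if ("trials" %in% names(pdf)) pdf$trials[m] else rep(trials, length(y))
  if (family == "poisson" && any(y < 0 | y != round(y)))
    stop("non-integer or negative Poisson phenotype at row ",
         which(y < 0 | y != round(y))[1])
  if (family == "binomial" && any(y < 0 | y > tr | y != round(y)))
    stop("binomial phenotype outside [0, trials] at row ",
         which(y < 0 | y > tr | y != round(y))[1])
  out <- list(map = map, geno = geno, pheno = y, trials = tr, ids = ids,
              design = design, family = family)
  class(out) <- "qtl_cross"
  out
}

#' @export
print.qtl_cross <- function(x, ...) {
  cat("QTL cross dataset: ", length(x$ids), " individuals, ",
      ncol(x$geno), " markers (", x$design, ", ", x$family, " trait)\n",
      sep = "")
  invisible(x)
}

#' Write a simulated (or read) cross to CSV files
#'
#' Writes `<prefix>_map.csv`, `<prefix>_geno.csv`, `<prefix>_pheno.csv`
#' and, for a simulated cross with QTLs, `<prefix>_truth.json` holding the
#' true QTL positions and effects.
#'
#' @param x A `"sim_cross"` or `"qtl_cross"`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the files written, invisibly.
#' @export
write_cross <- function(x, dir, prefix = "cross") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "sim_cross")) {
    map <- x$spec$map; geno <- x$marker_geno; y <- x$pheno
    design <- x$spec$design
    ids <- paste0("ind", seq_len(nrow(geno)))
    trials <- rep(x$spec$trials, nrow(geno))
  } else {
    map <- x$map; geno <- x$geno; y <- x$pheno; design <- x$design
    ids <- x$ids; trials <- x$trials
  }
  codes <- if (design == "f2") names(GENO_CODES$f2) else names(GENO_CODES$two)
  gchr <- matrix(codes[geno], nrow(geno), ncol(geno))
  gchr[is.na(gchr)] <- "-"
  paths <- c(map = file.path(dir, paste0(prefix, "_map.csv")),
             geno = file.path(dir, paste0(prefix, "_geno.csv")),
             pheno = file.path(dir, paste0(prefix, "_pheno.csv")))
  write_map_csv(map, paths["map"])
  gdf <- data.frame(id = ids, gchr, stringsAsFactors = FALSE)
  names(gdf) <- c("id", map$marker)
  utils::write.csv(gdf, paths["geno"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(id = ids, pheno = y, trials = trials),
                   paths["pheno"], row.names = FALSE, quote = FALSE)
  if (inherits(x, "sim_cross") && nrow(x$spec$qtl)) {
    paths <- c(paths, truth = file.path(dir, paste0(prefix, "_truth.json")))
    truth <- x$spec$qtl
    truth$genome_cM <- cumulative_position(map, truth$chrom, truth$pos_cM)
    jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE)
  }
  invisible(paths)
}

#' Run configuration for a genome scan
#'
#' Collects every knob a scan needs so a run is reproducible from the
#' config and seed alone; serializable to/from JSON.
#'
#' @param map,genotypes,phenotypes Input CSV paths.
#' @param design,family,link,trials Model settings.
#' @param grid_step Grid step in cM.
#' @param mode `"weighted"` or `"unweighted"`.
#' @param lambda_rule,lambda,cv_folds Penalty selection settings.
#' @param threshold Numeric critical value, or `NULL` to skip calling.
#' @param permutations If > 0 and `threshold` is `NULL`, number of phenotype
#'   permutations used to estimate the threshold.
#' @param level Genome-wide significance level.
#' @param seed Integer seed.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A `"run_config"` list.
#' @export
run_config <- function(map, genotypes, phenotypes, design = "backcross",
                       family = "binomial", link = NULL, trials = 1,
                       grid_step = 1, mode = "weighted", lambda_rule = "cv",
                       lambda = NULL, cv_folds = 5, threshold = NULL,
                       permutations = 0, level = 0.05, seed = 1,
                       out_dir = NULL) {
  cfg <- list(map = map, genotypes = genotypes, phenotypes = phenotypes,
              design = design, family = family, link = link, trials = trials,
              grid_step = grid_step, mode = mode, lambda_rule = lambda_rule,
              lambda = lambda, cv_folds = cv_folds, threshold = threshold,
              permutations = permutations, level = level, seed = seed,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration (JSON)
#' @param path JSON file path.
#' @return A `"run_config"`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg[!vapply(cfg, is.null, logical(1))])
}

#' @rdname read_config
#' @param cfg A `"run_config"`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run a genome scan from a configuration
#'
#' Reads the cross, builds the Haley-Knott regressors, fits the iteratively
#' reweighted LASSO, prunes and refits, and (given a threshold or a
#' permutation count) calls QTLs.  With `out_dir` set, writes
#' `scan.tsv` (one row per grid locus) and `qtl_report.json`.
#'
#' @param cfg A `"run_config"` (or path to its JSON).
#' @return List with `fit`, `summary`, `scan` (data frame), `calls`,
#'   `threshold`, `config`.
#' @export
run_scan <- function(cfg) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  cross <- read_cross(cfg$map, cfg$genotypes, cfg$phenotypes, cfg$design,
                      cfg$family, cfg$trials)
  grid <- locus_grid(cross$map, cfg$grid_step)
  rs <- build_regressors(cross$geno, grid, cross$design)
  fit <- irlasso(cross$pheno, rs, cfg$family, cfg$link, cross$trials,
                 mode = cfg$mode, lambda_rule = cfg$lambda_rule,
                 lambda = cfg$lambda, cv_folds = cfg$cv_folds,
                 seed = cfg$seed)
  threshold <- cfg$threshold
  if (is.null(threshold) && cfg$permutations > 0) {
    threshold <- qtl_threshold(
      list(pheno = cross$pheno, regressors = rs, trials = cross$trials,
           family = cfg$family, link = cfg$link),
      method = "permutation", n_replicates = cfg$permutations,
      level = cfg$level, seed = cfg$seed, mode = cfg$mode,
      lambda_rule = cfg$lambda_rule, lambda = cfg$lambda,
      cv_folds = cfg$cv_folds)
  }
  summ <- summary(fit, threshold = threshold)
  scan <- scan_table(fit, summ)
  out <- list(fit = fit, summary = summ, scan = scan, calls = summ$calls,
              threshold = threshold, config = cfg)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(scan, file.path(cfg$out_dir, "scan.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    cfg_rep <- cfg[!vapply(cfg, is.null, logical(1))]
    cfg_rep$out_dir <- NULL   # keep the report independent of where it lives
    report <- list(
      config = cfg_rep,
      lambda = fit$lambda, psi_range = range(fit$psi),
      outer_iterations = fit$outer_iterations,
      threshold = if (inherits(threshold, "qtl_threshold"))
        threshold$critical_value else threshold,
      qtls = if (!is.null(summ$calls)) summ$calls else summ$table)
    jsonlite::write_json(report, file.path(cfg$out_dir, "qtl_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# genome-wide scan table: one row per grid locus (additive columns)
scan_table <- function(fit, summ) {
  grid <- fit$regressors$grid
  des <- fit$design
  add <- which(des$type == "add")
  tab <- data.frame(chrom = grid$chrom[des$locus[add]],
                    pos_cM = grid$pos_cM[des$locus[add]],
                    genome_pos_cM = grid$genome_cM[des$locus[add]],
                    effect = unname(fit$coefficients[-1][add]),
                    se = NA_real_, t = NA_real_, neglog10p = NA_real_,
                    selected = FALSE, significant = FALSE)
  st <- summ$table[summ$table$type == "add", , drop = FALSE]
  i <- match(st$genome_cM, tab$genome_pos_cM)
  tab$selected[i] <- TRUE
  tab$effect[i] <- st$effect
  tab$se[i] <- st$se
  tab$t[i] <- st$t
  tab$neglog10p[i] <- st$neglog10p
  tab$significant[i] <- !is.na(st$significant) & st$significant
  tab
}

#' Reproduce the benchmark simulation experiment
#'
#' Runs the 10-QTL backcross scenario end to end for a trait and sample
#' size: estimates the genome-wide threshold from null-model simulations,
#' then runs replicate simulations scoring power, position and effect
#' recovery per QTL for the requested methods.
#'
#' @param trait `"binary"` or `"poisson"`.
#' @param n Sample size (200 or 400 in the benchmark).
#' @param methods Subset of `c("IRglmnet", "UWglmnet")`.
#' @param n_replicates Simulation replicates for power/parameter estimates.
#' @param threshold_replicates Null-simulation replicates for the threshold
#'   (1000 for the full protocol; reduce for desk-scale runs).
#' @param level Genome-wide significance level.
#' @param lambda_rule Penalty selection rule passed to [irlasso()]
#'   (default `"bic"`, the fast cross-validation-free mode).
#' @param grid_step Grid step in cM.
#' @param seed Integer seed.
#' @param threshold Optional precomputed `"qtl_threshold"` (skips the null
#'   simulations).
#' @return List with `threshold` and `power` (a `"qtl_power"` table).
#' @export
run_experiment <- function(trait = c("binary", "poisson"), n = 400,
                           methods = c("IRglmnet", "UWglmnet"),
                           n_replicates = 100, threshold_replicates = 200,
                           level = 0.05, lambda_rule = "bic", grid_step = 1,
                           seed = 1, threshold = NULL) {
  trait <- match.arg(trait)
  spec <- backcross_10qtl_spec(trait, n)
  if (is.null(threshold)) {
    threshold <- qtl_threshold(spec, method = "null_sim",
                               n_replicates = threshold_replicates,
                               level = level, seed = seed,
                               grid_step = grid_step,
                               lambda_rule = lambda_rule)
  }
  power <- power_experiment(spec, threshold, n_replicates = n_replicates,
                            methods = methods, grid_step = grid_step,
                            seed = seed + 1L, lambda_rule = lambda_rule)
  list(threshold = threshold, power = power)
}
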