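#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()].
#' Paths may be `NULL` when the `simulate` stage is enabled, in which
#' case the synthetic bundle supplies the inputs. Unknown keys passed to
#' [run_pipeline()] are rejected.
#'
#' @return Named list of configuration defaults.
#' @export
pipeline_config <- function() {
  list(
    tree = NULL, counts = NULL, lifestyles = NULL,
    alignment = NULL, site_map = NULL, pod_tree = NULL,
    out_dir = "lignodecay-run",
    simulate = TRUE, preset = list(),
    stages = c("bdp", "lifestyles", "ordination", "diversity"),
    seed = 1,
    n_sim = 1000, alpha_family = 0.01, alpha_branch = 0.05,
    n_perm = 999,
    wknn_features = "fast", wknn_scale = TRUE,
    tail_threshold = 16
  )
}

#' Run the full inference pipeline
#'
#' Orchestrates the stages end-to-end: input simulation or loading,
#' birth-death fit with fast-family detection and ancestral repertoires,
#' weighted-kNN lifestyle tuning and ancestral lifestyle prediction,
#' phylogenetic PCA + PERMANOVA, the diversity index, and (when an
#' alignment is supplied) POD typing, ancestral-residue reconstruction
#' and type-origin mapping. All outputs are written as TSV/Newick under
#' `out_dir` together with a JSON run manifest (parameters, seeds,
#' checksums); outputs are pure functions of (inputs, config).
#'
#' @param config Named list overriding entries of [pipeline_config()],
#'   or a path to a YAML file with the same keys.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  if (isTRUE(cfg$simulate)) {
    preset <- do.call(decay_preset, c(cfg$preset,
                                      if (is.null(cfg$preset$seed))
                                        list(seed = cfg$seed)))
    bundle <- simulate_bundle(preset, dir = file.path(cfg$out_dir, "inputs"))
    tree <- bundle$tree
    counts <- bundle$tip_counts
    lifestyles <- bundle$lifestyles[tree$tip.label]
    res$bundle <- bundle
  } else {
    if (is.null(cfg$tree) || is.null(cfg$counts))
      stop("tree and counts paths are required when simulate = FALSE")
    tree <- read_timetree(cfg$tree)
    counts <- read_counts(cfg$counts)
    lifestyles <- if (!is.null(cfg$lifestyles)) read_lifestyles(cfg$lifestyles)
                  else NULL
    if (is.null(lifestyles) && "lifestyles" %in% cfg$stages)
      stop("lifestyle stage enabled but no lifestyles file: ",
           deparse(cfg$lifestyles))
  }
  rep <- validate_bundle(tree, counts, lifestyles)
  if (nrow(rep)) stop("inconsistent inputs:\n",
                      paste(rep$check, rep$detail, collapse = "\n"))

  if ("bdp" %in% cfg$stages) {
    fit <- bdp_fit(tree, counts, n_sim = cfg$n_sim, seed = cfg$seed,
                   alpha = cfg$alpha_family)
    write_tsv(fit$family_table, file.path(cfg$out_dir, "family_table.tsv"),
              rownames_as = NULL)
    write_tsv(fit$ancestral, file.path(cfg$out_dir, "ancestral_counts.tsv"),
              rownames_as = "node")
    for (f in fit$fast_families)
      write_tsv(fit$branch_tables[[f]],
                file.path(cfg$out_dir, paste0("branches_", f, ".tsv")),
                rownames_as = NULL)
    res$bdp <- fit
  }

  if ("lifestyles" %in% cfg$stages) {
    feats <- if (identical(cfg$wknn_features, "fast") && length(res$bdp$fast_families))
      res$bdp$fast_families else colnames(counts)
    tune <- wknn_tune(counts[, feats, drop = FALSE],
                      lifestyles[rownames(counts)], scale = cfg$wknn_scale)
    anc_X <- res$bdp$ancestral[tree$node.label, feats, drop = FALSE]
    pred <- predict_ancestral_lifestyles(tune$model, anc_X)
    write_tsv(tune$grid, file.path(cfg$out_dir, "wknn_grid.tsv"),
              rownames_as = NULL)
    write_tsv(pred, file.path(cfg$out_dir, "ancestral_lifestyles.tsv"),
              rownames_as = "node")
    res$lifestyles <- list(tuning = tune, ancestral = pred)
  }

  if ("ordination" %in% cfg$stages) {
    role <- attr(counts, "role")
    X <- if (!is.null(role)) counts[, role[colnames(counts)] == "focal",
                                    drop = FALSE] else counts
    pc <- ppca(tree, X)
    anc <- ancestral_scores(tree, pc$scores)
    pv <- permanova(pc$scores, lifestyles[rownames(pc$scores)],
                    n_perm = cfg$n_perm, seed = cfg$seed)
    pw <- pairwise_permanova_fdr(pc$scores, lifestyles[rownames(pc$scores)],
                                 n_perm = cfg$n_perm, seed = cfg$seed)
    write_tsv(rbind(pc$scores, anc), file.path(cfg$out_dir, "ppca_scores.tsv"),
              rownames_as = "node")
    write_tsv(data.frame(component = seq_along(pc$eigenvalues),
                         eigenvalue = pc$eigenvalues,
                         percent_var = pc$percent_var),
              file.path(cfg$out_dir, "ppca_eigen.tsv"), rownames_as = NULL)
    write_tsv(pw, file.path(cfg$out_dir, "permanova_pairwise.tsv"),
              rownames_as = NULL)
    res$ordination <- list(ppca = pc, ancestral = anc,
                           permanova = pv, pairwise = pw)
  }

  if ("diversity" %in% cfg$stages) {
    groups <- split(rownames(counts), lifestyles[rownames(counts)])
    div <- vapply(groups, function(sp)
      diversity_index(colMeans(counts[sp, , drop = FALSE])), numeric(1))
    div <- c(div, overall = diversity_index(colMeans(counts)))
    dtab <- data.frame(group = names(div), diversity = unname(div))
    write_tsv(dtab, file.path(cfg$out_dir, "diversity.tsv"),
              rownames_as = NULL)
    res$diversity <- dtab
  }

  if ("pod" %in% cfg$stages) {
    if (is.null(cfg$alignment) || is.null(cfg$site_map) ||
        is.null(cfg$pod_tree))
      stop("pod stage needs alignment, site_map and pod_tree paths")
    msa <- read_msa(cfg$alignment)
    sm <- read_site_map(cfg$site_map, alignment_length = nchar(msa[[1]]))
    ptree <- read_substtree(cfg$pod_tree)
    tip_types <- vapply(names(msa), function(id)
      as.character(classify_pod(extract_profile(msa, sm, id),
                                cfg$tail_threshold)), character(1))
    cols <- unlist(sm)
    asr <- marginal_asr(ptree, msa, cols)
    anc_types <- classify_ancestors(asr, sm,
                                    tail_threshold = cfg$tail_threshold)
    write_tsv(data.frame(sequence = names(tip_types),
                         type = unname(tip_types)),
              file.path(cfg$out_dir, "pod_types.tsv"), rownames_as = NULL)
    write_tsv(anc_types, file.path(cfg$out_dir, "pod_ancestral_types.tsv"),
              rownames_as = NULL)
    res$pod <- list(tip_types = tip_types, ancestral = anc_types)
  }

  manifest <- list(
    package = "lignodecay",
    version = as.character(packageVersion("lignodecay")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = cfg[c("n_sim", "alpha_family", "alpha_branch", "n_perm",
                       "wknn_features", "tail_threshold")],
    outputs = {
      fs <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
      fs <- fs[!grepl("manifest.json$", fs)]
      as.list(setNames(unname(tools::md5sum(fs)),
                       sub(paste0("^", cfg$out_dir, "/?"), "", fs)))
    }
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
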