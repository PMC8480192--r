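#' The closed set of decay lifestyles
#'
#' The six lignocellulose-decay lifestyles used throughout: white rot,
#' brown rot, decayed wood, grass litter, forest litter and mycorrhiza.
#'
#' @return Character vector of the six lifestyle codes.
#' @export
lifestyle_levels <- function() {
  c("white_rot", "brown_rot", "decayed_wood",
    "grass_litter", "forest_litter", "mycorrhiza")
}

#' Read a gene-family copy-number matrix
#'
#' Reads a TSV with family ids in the header row and species ids in the
#' first column. All cells must be non-negative integers; lines starting
#' with `#` are treated as comments.
#'
#' @param path TSV file path.
#' @param roles Optional named character vector mapping family ids to a
#'   role tag (`"focal"` for PCWDE-like families, `"background"` otherwise);
#'   stored as the `"role"` attribute.
#' @return Integer matrix (species x families) with dimnames.
#' @export
read_counts <- function(path, roles = NULL) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs a species column plus >= 1 family")
  sp <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in count table")
  if (anyNA(m)) stop("missing cells in count table")
  if (any(m < 0)) stop("negative counts are not allowed")
  if (any(abs(m - round(m)) > 1e-9)) stop("counts must be integers")
  storage.mode(m) <- "integer"
  rownames(m) <- sp
  if (anyDuplicated(sp)) stop("duplicate species ids in count table")
  if (is.null(colnames(m)) || any(!nzchar(colnames(m))))
    stop("every family column needs a name")
  if (!is.null(roles)) attr(m, "role") <- roles[colnames(m)]
  m
}

#' Write a count matrix (or any matrix/data frame) as TSV
#'
#' Byte-deterministic writer: fixed column order, no quoting, `\n` line
#' endings.
#'
#' @param x Matrix or data frame; row names become the first column when
#'   `rownames_as` is non-`NULL`.
#' @param path Output path.
#' @param rownames_as Column name for the row names, or `NULL`.
#' @export
write_tsv <- function(x, path, rownames_as = "id") {
  if (!is.null(rownames_as) && !is.null(rownames(x))) {
    x <- data.frame(setNames(list(rownames(x)), rownames_as),
                    as.data.frame(x, check.names = FALSE),
                    check.names = FALSE)
  }
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a lifestyle table
#'
#' TSV with columns `id` and `lifestyle`; every lifestyle must be one of
#' [lifestyle_levels()].
#'
#' @param path TSV file path.
#' @return Named character vector (names = species/node ids).
#' @export
read_lifestyles <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("id", "lifestyle") %in% names(df)))
    stop("lifestyle table needs columns 'id' and 'lifestyle'")
  bad <- setdiff(unique(df$lifestyle), lifestyle_levels())
  if (length(bad))
    stop("unknown lifestyles: ", paste(bad, collapse = ", "))
  setNames(df$lifestyle, df$id)
}

#' Read / write an amino-acid alignment (FASTA)
#'
#' Sequences must be equal-length aligned strings over the 20 amino acids
#' plus gap `-` and `X`.
#'
#' @param path FASTA file path.
#' @return Named character vector of aligned sequences.
#' @export
read_msa <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  id <- sub("^>\\s*", "", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  names(seqs) <- id
  validate_msa(seqs)
  seqs
}

#' @rdname read_msa
#' @param seqs Named character vector of aligned sequences.
#' @export
write_msa <- function(seqs, path) {
  validate_msa(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

validate_msa <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1) stop("aligned sequences differ in length")
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX-]*$", toupper(seqs))
  if (!all(ok)) stop("alignment contains characters outside the amino-acid alphabet")
  invisible(TRUE)
}

#' Site map for class-II peroxidase catalytic columns
#'
#' Names the 1-based alignment columns carrying the catalytic machinery:
#' distal His/Arg pair, proximal His, the three Mn(2+)-oxidation-site
#' positions, the lignin-oxidising surface Trp position, the surface Tyr
#' position, and the last conserved column before the C-terminal tail.
#'
#' @param distal_his,distal_arg,proximal_his,mn_site_1,mn_site_2,mn_site_3,trp_lip,tyr_tc,tail_anchor
#'   1-based alignment column indices.
#' @param alignment_length Optional total column count used to bound-check.
#' @return A named list of class `pod_site_map`.
#' @export
pod_site_map <- function(distal_his, distal_arg, proximal_his,
                         mn_site_1, mn_site_2, mn_site_3,
                         trp_lip, tyr_tc, tail_anchor,
                         alignment_length = NULL) {
  sm <- list(distal_his = distal_his, distal_arg = distal_arg,
             proximal_his = proximal_his, mn_site_1 = mn_site_1,
             mn_site_2 = mn_site_2, mn_site_3 = mn_site_3,
             trp_lip = trp_lip, tyr_tc = tyr_tc, tail_anchor = tail_anchor)
  v <- unlist(sm)
  if (any(v < 1) || any(v != round(v))) stop("site-map columns must be positive integers")
  if (anyDuplicated(v)) stop("site-map columns must be distinct")
  if (!is.null(alignment_length) && any(v > alignment_length))
    stop("site-map column outside alignment")
  structure(lapply(sm, as.integer), class = "pod_site_map")
}

#' Read a site map from YAML
#'
#' @param path YAML file with the nine keys of [pod_site_map()].
#' @param alignment_length Optional bound check.
#' @return A `pod_site_map`.
#' @export
read_site_map <- function(path, alignment_length = NULL) {
  y <- yaml::read_yaml(path)
  do.call(pod_site_map, c(y, list(alignment_length = alignment_length)))
}

#' Cross-validate a tree / count-matrix / lifestyle bundle
#'
#' Report-only check of the id cross-references: tree tips vs count-matrix
#' rows vs lifestyle ids, plus label-set validity. An empty report means
#' the bundle is consistent.
#'
#' @param tree A `phylo` (or `NULL` to skip tree checks).
#' @param counts Count matrix (or `NULL`).
#' @param lifestyles Named lifestyle vector (or `NULL`).
#' @return Data frame with columns `check` and `detail`, one row per
#'   mismatch; zero rows when valid.
#' @export
validate_bundle <- function(tree = NULL, counts = NULL, lifestyles = NULL) {
  rep <- list()
  add <- function(check, items) {
    if (length(items))
      rep[[length(rep) + 1]] <<- data.frame(check = check, detail = items)
  }
  if (!is.null(tree) && !is.null(counts)) {
    add("species_in_counts_not_tree", setdiff(rownames(counts), tree$tip.label))
    add("tree_tip_not_in_counts", setdiff(tree$tip.label, rownames(counts)))
  }
  if (!is.null(tree) && !is.null(lifestyles)) {
    add("tree_tip_without_lifestyle",
        setdiff(tree$tip.label, names(lifestyles)))
  }
  if (!is.null(lifestyles)) {
    add("unknown_lifestyle",
        unique(lifestyles[!lifestyles %in% lifestyle_levels()]))
  }
  if (length(rep)) do.call(rbind, rep)
  else data.frame(check = character(), detail = character())
}
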