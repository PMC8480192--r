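#' The closed set of class-II peroxidase (POD) types
#'
#' Lignin peroxidase (LiP), versatile peroxidase (VP), atypical VP
#' (VP-a), short/long classical manganese peroxidases (MnP-s, MnP-l),
#' the alternative Mn-site subfamilies (MnP-ESD, MnP-DGD, MnP-DED), the
#' His/His new POD (NPOD), the non-ligninolytic generic peroxidase (GP),
#' and `unclassified`.
#'
#' @return Character vector of the eleven type codes.
#' @export
pod_types <- function() {
  c("LiP", "VP", "VP-a", "MnP-s", "MnP-l", "MnP-ESD", "MnP-DGD",
    "MnP-DED", "NPOD", "GP", "unclassified")
}

.AA <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

#' Extract the catalytic-site profile of one aligned sequence
#'
#' Reads the residues at the mapped catalytic columns and counts the
#' C-terminal tail length (non-gap residues after the tail-anchor
#' column).
#'
#' @param msa Named character vector of aligned sequences
#'   (see [read_msa()]).
#' @param site_map A [pod_site_map()].
#' @param seq_id Sequence identifier.
#' @return List of class `pod_profile` with the residues at
#'   `distal_his`, `distal_arg`, `proximal_his`, `mn_site_1..3`,
#'   `trp_lip`, `tyr_tc`, and `c_tail_length`.
#' @export
extract_profile <- function(msa, site_map, seq_id) {
  if (!seq_id %in% names(msa)) stop("sequence not in alignment: ", seq_id)
  s <- toupper(msa[[seq_id]])
  L <- nchar(s)
  cols <- unlist(site_map)
  if (any(cols > L)) stop("site-map column outside alignment")
  res <- function(col) substr(s, col, col)
  tail_seq <- substr(s, site_map$tail_anchor + 1, L)
  prof <- list(distal_his = res(site_map$distal_his),
               distal_arg = res(site_map$distal_arg),
               proximal_his = res(site_map$proximal_his),
               mn_site_1 = res(site_map$mn_site_1),
               mn_site_2 = res(site_map$mn_site_2),
               mn_site_3 = res(site_map$mn_site_3),
               trp_lip = res(site_map$trp_lip),
               tyr_tc = res(site_map$tyr_tc),
               c_tail_length = nchar(gsub("-", "", tail_seq)))
  structure(prof, class = "pod_profile")
}

.mn_triads <- list(canonical = c("E", "E", "D"),
                   ESD = c("E", "S", "D"),
                   DGD = c("D", "G", "D"),
                   DED = c("D", "E", "D"))

#' Classify a POD sequence from its catalytic residues
#'
#' Rule-based decision over the catalytic-site profile:
#' \enumerate{
#'   \item A His/His distal pair marks the new POD type (NPOD); any
#'     other departure from the conserved His/Arg pair is
#'     `unclassified`.
#'   \item The Mn(2+)-oxidation triad is matched against Glu/Glu/Asp
#'     (canonical), Glu/Ser/Asp (ESD), Asp/Gly/Asp (DGD) and
#'     Asp/Glu/Asp (DED).
#'   \item A Trp at the surface-tryptophan position combined with a
#'     complete acidic triad (canonical or DED) gives VP; with a triad
#'     retaining exactly two acidic residues it gives the atypical VP-a;
#'     with no Mn site it gives LiP.
#'   \item Without the Trp: the canonical triad gives MnP (long or
#'     short by C-terminal tail length against `tail_threshold`), the
#'     alternative triads give MnP-ESD / MnP-DGD / MnP-DED, and no
#'     triad gives the generic peroxidase GP.
#' }
#' A surface Tyr without the His/His pair is recorded as an annotation
#' attribute (`tyr_flag`), not a distinct type.
#'
#' @param profile A `pod_profile` from [extract_profile()].
#' @param tail_threshold Minimum tail length (residues past the anchor)
#'   for the long-MnP call (default 16).
#' @return A single type from [pod_types()], with attribute `tyr_flag`.
#' @export
classify_pod <- function(profile, tail_threshold = 16) {
  distal <- c(profile$distal_his, profile$distal_arg)
  tyr_flag <- identical(profile$tyr_tc, "Y")
  out <- function(type) structure(type, tyr_flag = tyr_flag)
  if (any(distal %in% c("-", "X"))) return(out("unclassified"))
  if (identical(distal, c("H", "H"))) return(out("NPOD"))
  if (!identical(distal, c("H", "R"))) return(out("unclassified"))
  triad <- c(profile$mn_site_1, profile$mn_site_2, profile$mn_site_3)
  tri_name <- "none"
  for (nm in names(.mn_triads))
    if (identical(triad, .mn_triads[[nm]])) { tri_name <- nm; break }
  n_acidic <- sum(triad %in% c("D", "E"))
  has_trp <- identical(profile$trp_lip, "W")
  if (has_trp) {
    if (tri_name %in% c("canonical", "DED")) return(out("VP"))
    if (n_acidic == 2) return(out("VP-a"))
    return(out("LiP"))
  }
  switch(tri_name,
    canonical = if (profile$c_tail_length >= tail_threshold)
      out("MnP-l") else out("MnP-s"),
    ESD = out("MnP-ESD"),
    DGD = out("MnP-DGD"),
    DED = out("MnP-DED"),
    none = out("GP"))
}

#' Amino-acid substitution model for ancestral reconstruction
#'
#' Builds the rate matrix Q (normalised to one expected substitution per
#' unit branch length at stationarity) and the stationary frequencies.
#' `"WAG"` uses the WAG exchangeabilities and frequencies; `"uniform"`
#' is an equal-rates (Jukes-Cantor-like) model, optionally on a reduced
#' alphabet (useful for exact enumeration checks).
#'
#' @param model `"WAG"` or `"uniform"`.
#' @param alphabet State alphabet; defaults to the 20 amino acids.
#' @return List with `alphabet`, `Q`, `freqs`.
#' @export
aa_model <- function(model = c("WAG", "uniform"), alphabet = NULL) {
  model <- match.arg(model)
  if (model == "WAG") {
    if (!is.null(alphabet) && !identical(alphabet, .AA))
      stop("WAG is defined on the 20 amino acids")
    alphabet <- .AA
    Q <- NULL; bf <- NULL
    # exchangeabilities + frequencies from the installed phangorn
    phangorn:::getModelAA("WAG", bf = TRUE, Q = TRUE)
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- Q
    S <- S + t(S)
    # phangorn's amino-acid order: ARNDCQEGHILKMFPSTWYV (matches .AA)
    pi <- bf / sum(bf)
  } else {
    if (is.null(alphabet)) alphabet <- .AA
    n <- length(alphabet)
    S <- matrix(1, n, n); diag(S) <- 0
    pi <- rep(1 / n, n)
  }
  Qm <- S %*% diag(pi)
  diag(Qm) <- 0
  diag(Qm) <- -rowSums(Qm)
  scale <- -sum(pi * diag(Qm))
  Qm <- Qm / scale
  dimnames(Qm) <- list(alphabet, alphabet)
  list(alphabet = alphabet, Q = Qm, freqs = setNames(pi, alphabet))
}

# P(t) = expm(Q t) via symmetric eigendecomposition in the pi^(1/2) basis.
.aa_pmat <- function(model, t) {
  pi <- model$freqs
  B <- diag(sqrt(pi)) %*% model$Q %*% diag(1 / sqrt(pi))
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / sqrt(pi)) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(sqrt(pi))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Marginal ancestral reconstruction of alignment columns
#'
#' Felsenstein pruning per column, then the standard outside pass to
#' obtain the marginal posterior distribution over states at every
#' internal node, under the model's stationary root prior. Gaps and `X`
#' are treated as missing data (flat partial likelihood).
#'
#' @param tree Tree with branch lengths in expected substitutions/site;
#'   tip labels must match the sequence names.
#' @param msa Named character vector of aligned sequences.
#' @param columns 1-based alignment columns to reconstruct.
#' @param model An [aa_model()] (default WAG).
#' @return Array internal-nodes x columns x states of posterior
#'   probabilities (each state vector sums to 1), with dimnames.
#' @export
marginal_asr <- function(tree, msa, columns, model = aa_model("WAG")) {
  miss <- setdiff(tree$tip.label, names(msa))
  if (length(miss)) stop("tips without sequences: ", paste(miss, collapse = ", "))
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  ns <- length(model$alphabet)
  Pm <- lapply(tree$edge.length, function(t) .aa_pmat(model, t))
  parent <- integer(n_node); parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of <- integer(n_node); edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  children <- split(tree$edge[, 2], tree$edge[, 1])
  post <- array(NA_real_,
                dim = c(tree$Nnode, length(columns), ns),
                dimnames = list(tree$node.label, as.character(columns),
                                model$alphabet))
  for (ci in seq_along(columns)) {
    col <- columns[ci]
    # tip partial likelihoods
    Lk <- matrix(1, ns, n_node)
    for (v in seq_len(n_tip)) {
      ch <- toupper(substr(msa[[tree$tip.label[v]]], col, col))
      if (ch %in% model$alphabet) {
        Lk[, v] <- 0
        Lk[match(ch, model$alphabet), v] <- 1
      } else if (!ch %in% c("-", "X", "")) {
        stop("residue outside alphabet at column ", col, ": ", ch)
      }
    }
    # inside (pruning) pass
    up <- matrix(1, ns, n_node)  # message from child (incl. its branch) to parent
    for (e in postorder_edges(tree)) {
      par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
      if (chi > n_tip) {
        kids <- children[[as.character(chi)]]
        for (kk in kids) Lk[, chi] <- Lk[, chi] * up[, kk]
      }
      up[, chi] <- Pm[[e]] %*% Lk[, chi]
    }
    root <- n_tip + 1L
    kids <- children[[as.character(root)]]
    for (kk in kids) Lk[, root] <- Lk[, root] * up[, kk]
    # outside pass
    down <- matrix(0, ns, n_node)
    down[, root] <- model$freqs
    for (v in preorder_nodes(tree)) {
      if (v <= n_tip) next
      kids <- children[[as.character(v)]]
      for (kk in kids) {
        if (kk <= n_tip) next
        sib_prod <- rep(1, ns)
        for (ss in setdiff(kids, kk)) sib_prod <- sib_prod * up[, ss]
        down[, kk] <- t(Pm[[edge_of[kk]]]) %*% (down[, v] * sib_prod)
      }
    }
    for (v in (n_tip + 1L):n_node) {
      w <- Lk[, v] * down[, v]
      post[v - n_tip, ci, ] <- w / sum(w)
    }
  }
  post
}

#' Classify reconstructed POD ancestors
#'
#' Takes the modal residue of each catalytic column from the marginal
#' posteriors, assembles a catalytic profile per internal node and runs
#' [classify_pod()]. When the modal probability at any decisive column
#' falls below `ambiguity_threshold`, a runner-up type (recomputed with
#' the second-best residue at the least certain column) is reported
#' alongside.
#'
#' @param asr Posterior array from [marginal_asr()]; its columns must
#'   cover the catalytic positions of `site_map`.
#' @param site_map A [pod_site_map()].
#' @param tail_policy Tail length assumed for ancestors: `"short"`
#'   (default, the ancestral condition), `"long"`, or a number.
#' @param tail_threshold Passed to [classify_pod()].
#' @param ambiguity_threshold Modal-probability cutoff below which the
#'   runner-up type is reported (default 0.7).
#' @return Data frame per internal node: `node`, `type`, `runner_up`
#'   (`NA` when unambiguous), `min_prob` (smallest decisive modal
#'   probability).
#' @export
classify_ancestors <- function(asr, site_map, tail_policy = "short",
                               tail_threshold = 16,
                               ambiguity_threshold = 0.7) {
  tail_len <- if (is.numeric(tail_policy)) tail_policy
              else if (tail_policy == "long") tail_threshold
              else 0
  dec_cols <- c(distal_his = site_map$distal_his,
                distal_arg = site_map$distal_arg,
                mn_site_1 = site_map$mn_site_1,
                mn_site_2 = site_map$mn_site_2,
                mn_site_3 = site_map$mn_site_3,
                trp_lip = site_map$trp_lip)
  all_cols <- c(dec_cols, proximal_his = site_map$proximal_his,
                tyr_tc = site_map$tyr_tc)
  av <- dimnames(asr)[[2]]
  need <- as.character(all_cols)
  if (!all(need %in% av)) stop("posteriors missing for catalytic columns")
  nodes <- dimnames(asr)[[1]]
  res <- lapply(seq_along(nodes), function(i) {
    modal <- function(col, rank = 1) {
      pv <- asr[i, as.character(col), ]
      names(sort(pv, decreasing = TRUE))[rank]
    }
    prof <- structure(list(
      distal_his = modal(site_map$distal_his),
      distal_arg = modal(site_map$distal_arg),
      proximal_his = modal(site_map$proximal_his),
      mn_site_1 = modal(site_map$mn_site_1),
      mn_site_2 = modal(site_map$mn_site_2),
      mn_site_3 = modal(site_map$mn_site_3),
      trp_lip = modal(site_map$trp_lip),
      tyr_tc = modal(site_map$tyr_tc),
      c_tail_length = tail_len), class = "pod_profile")
    type <- classify_pod(prof, tail_threshold)
    probs <- vapply(dec_cols, function(col)
      max(asr[i, as.character(col), ]), numeric(1))
    minp <- min(probs)
    runner <- NA_character_
    if (minp < ambiguity_threshold) {
      weak <- names(dec_cols)[which.min(probs)]
      prof2 <- prof
      prof2[[weak]] <- modal(dec_cols[[weak]], rank = 2)
      runner <- as.character(classify_pod(prof2, tail_threshold))
    }
    data.frame(node = nodes[i], type = as.character(type),
               runner_up = runner, min_prob = minp)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Map the origins of each POD type on the dated species tree
#'
#' For every type present, reports each node bearing the type whose
#' parent bears a different one (the root counts as an origin). Multiple
#' independent (convergent) origins are all reported; the first
#' appearance of a type is its oldest origin.
#'
#' @param time_tree Ultrametric time tree (ages derivable).
#' @param node_types Named type per node (tips and internal nodes).
#' @return Data frame `type`, `node`, `age_My`, `parent_type`, sorted by
#'   type then decreasing age; attribute `first_appearance` gives the
#'   oldest origin per type.
#' @export
map_type_origins <- function(time_tree, node_types) {
  ids <- node_ids(time_tree)
  miss <- setdiff(ids, names(node_types))
  if (length(miss)) stop("types missing for nodes: ", paste(head(miss), collapse = ", "))
  ages <- node_ages(time_tree)
  n_tip <- length(time_tree$tip.label)
  parent <- integer(length(ids)); parent[time_tree$edge[, 2]] <- time_tree$edge[, 1]
  root <- n_tip + 1L
  rows <- lapply(seq_along(ids), function(v) {
    ty <- node_types[[ids[v]]]
    pty <- if (v == root) NA_character_ else node_types[[ids[parent[v]]]]
    if (v == root || !identical(ty, pty))
      data.frame(type = ty, node = ids[v], age_My = ages[[ids[v]]],
                 parent_type = pty)
    else NULL
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$type, -out$age_My, out$node), ]
  rownames(out) <- NULL
  first <- out[!duplicated(out$type), ]
  attr(out, "first_appearance") <- first
  out
}
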