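# Co-cluster assignment, ranking, and biomarker extraction from a fit.

#' Assign genes and DCCs to co-clusters
#'
#' Each gene goes to the component maximizing `Pr(G_i | H_r)` and each
#' DCC to the component maximizing `Pr(C_j | H_r)`. Ties are broken to
#' the lowest component index, so the assignment is deterministic.
#'
#' @param fit A `"phvm"` fit or a `"phvm_params"` object.
#' @return List with integer vectors `gene` and `dcc` of labels in
#'   `1..k`, named after the fitted matrix dimnames when available.
#' @export
assign_coclusters <- function(fit) {
  params <- if (inherits(fit, "phvm")) fit$params else fit
  gene <- apply(params$p_g_given_h, 1, which.max)
  dcc <- apply(params$p_c_given_h, 1, which.max)
  if (inherits(fit, "phvm") && !is.null(fit$dimnames)) {
    names(gene) <- fit$dimnames[[1]]
    names(dcc) <- fit$dimnames[[2]]
  }
  list(gene = as.integer(gene) |> stats::setNames(names(gene)),
       dcc = as.integer(dcc) |> stats::setNames(names(dcc)))
}

#' Rank co-clusters by average joint probability
#'
#' For every co-cluster `r`, averages the model joint probability
#' `Pr(G_i, C_j)` over the cells whose gene and DCC are both labeled
#' `r`. Co-clusters are ranked in decreasing order of this average; the
#' one with the smallest average holds the non-biomarker genes together
#' with the non-regulatory DCCs and is declared the background
#' co-cluster. A co-cluster with no genes or no DCCs has an undefined
#' average and is ranked below every populated co-cluster, with a
#' warning.
#'
#' @param labels Assignment list from [assign_coclusters()].
#' @param joint Gene x DCC joint-probability matrix, e.g.
#'   `phvm_joint_probability(fit$params)`.
#' @return Object of class `"cocluster_result"`: `gene_labels`,
#'   `dcc_labels`, `joint`, `avg_joint_per_cocluster` (length `k`, `NA`
#'   for empty co-clusters), `cocluster_rank` (component indices in
#'   decreasing order of average) and `background_cocluster`.
#' @export
rank_coclusters <- function(labels, joint) {
  k <- max(labels$gene, labels$dcc)
  avg <- vapply(seq_len(k), function(r) {
    gi <- labels$gene == r
    cj <- labels$dcc == r
    if (!any(gi) || !any(cj)) NA_real_ else mean(joint[gi, cj, drop = FALSE])
  }, numeric(1))
  if (anyNA(avg)) {
    warning("co-cluster(s) ", paste(which(is.na(avg)), collapse = ", "),
            " contain no genes or no DCCs; ranked last with undefined ",
            "average joint probability", call. = FALSE)
  }
  rank_order <- order(avg, decreasing = TRUE, na.last = TRUE)
  structure(list(gene_labels = labels$gene, dcc_labels = labels$dcc,
                 joint = joint, avg_joint_per_cocluster = avg,
                 cocluster_rank = rank_order,
                 background_cocluster = rank_order[k]),
            class = "cocluster_result")
}

#' @export
print.cocluster_result <- function(x, ...) {
  k <- length(x$avg_joint_per_cocluster)
  cat("Co-clustering of", length(x$gene_labels), "genes and",
      length(x$dcc_labels), "DCCs into", k, "co-clusters\n")
  tab <- data.frame(
    cocluster = x$cocluster_rank,
    n_genes = vapply(x$cocluster_rank,
                     function(r) sum(x$gene_labels == r), integer(1)),
    n_dccs = vapply(x$cocluster_rank,
                    function(r) sum(x$dcc_labels == r), integer(1)),
    avg_joint = signif(x$avg_joint_per_cocluster[x$cocluster_rank], 7))
  print(tab, row.names = FALSE)
  cat("Background co-cluster:", x$background_cocluster, "\n")
  invisible(x)
}

#' Extract biomarker genes, regulatory DCCs, directions and rankings
#'
#' Every non-background co-cluster is a biomarker co-cluster: its genes
#' are the biomarker genes and its DCCs their regulatory doses. Each
#' (gene, DCC) pair within a biomarker co-cluster is called up- or
#' down-regulated from the sign of the signed mean fold change. DCCs
#' are scored by their average joint probability `Z_j` over the
#' biomarker genes of their own co-cluster, rescaled so the best DCC
#' scores exactly 100; gene-DCC pairs are scored the same way from the
#' cellwise joint probabilities `Z_ij`.
#'
#' @param cc A `"cocluster_result"`.
#' @param fold The signed gene x DCC fold-change matrix (before taking
#'   absolute values); row/column order must match the fit.
#' @return Object of class `"biomarker_report"`: `biomarker_genes`,
#'   `regulatory_dccs` (character or index vectors), `direction`
#'   (data frame: gene, cocluster, dcc, direction), `dcc_scores`
#'   (data frame: dcc, cocluster, avg_joint, score, sorted decreasing)
#'   and `pair_scores` (data frame: dcc, gene, joint, score). With
#'   `k = 1` there is no biomarker co-cluster and an empty report is
#'   returned with a warning.
#' @export
extract_biomarkers <- function(cc, fold) {
  stopifnot(inherits(cc, "cocluster_result"))
  fold <- as.matrix(fold)
  gene_ids <- .ids(cc$gene_labels, rownames(fold), "gene")
  dcc_ids <- .ids(cc$dcc_labels, colnames(fold), "dcc")
  k <- length(cc$avg_joint_per_cocluster)
  biom <- setdiff(cc$cocluster_rank, cc$background_cocluster)
  biom <- biom[!is.na(cc$avg_joint_per_cocluster[biom])]
  if (k == 1 || length(biom) == 0) {
    warning("no biomarker co-cluster (k = 1); returning an empty report",
            call. = FALSE)
    return(structure(list(biomarker_genes = character(0),
                          regulatory_dccs = character(0),
                          direction = data.frame(),
                          dcc_scores = data.frame(),
                          pair_scores = data.frame()),
                     class = "biomarker_report"))
  }

  direction <- list()
  z_dcc <- list()
  z_pair <- list()
  for (r in biom) {
    gi <- which(cc$gene_labels == r)
    cj <- which(cc$dcc_labels == r)
    sub_fold <- fold[gi, cj, drop = FALSE]
    sub_joint <- cc$joint[gi, cj, drop = FALSE]
    direction[[length(direction) + 1L]] <- data.frame(
      gene = rep(gene_ids[gi], times = length(cj)),
      cocluster = r,
      dcc = rep(dcc_ids[cj], each = length(gi)),
      direction = ifelse(as.vector(sub_fold) > 0, "up",
                         ifelse(as.vector(sub_fold) < 0, "down", "none")),
      stringsAsFactors = FALSE)
    z_dcc[[length(z_dcc) + 1L]] <- data.frame(
      dcc = dcc_ids[cj], cocluster = r,
      avg_joint = colMeans(sub_joint), stringsAsFactors = FALSE)
    z_pair[[length(z_pair) + 1L]] <- data.frame(
      dcc = rep(dcc_ids[cj], each = length(gi)),
      gene = rep(gene_ids[gi], times = length(cj)),
      cocluster = r,
      joint = as.vector(sub_joint), stringsAsFactors = FALSE)
  }
  dcc_scores <- do.call(rbind, z_dcc)
  dcc_scores$score <- 100 * dcc_scores$avg_joint / max(dcc_scores$avg_joint)
  dcc_scores <- dcc_scores[order(dcc_scores$score, decreasing = TRUE), ]
  rownames(dcc_scores) <- NULL

  pair_scores <- do.call(rbind, z_pair)
  pair_scores$score <- 100 * pair_scores$joint / max(pair_scores$joint)
  pair_scores <- pair_scores[order(pair_scores$score, decreasing = TRUE), ]
  rownames(pair_scores) <- NULL

  structure(list(
    biomarker_genes = gene_ids[cc$gene_labels %in% biom],
    regulatory_dccs = dcc_ids[cc$dcc_labels %in% biom],
    direction = do.call(rbind, direction),
    dcc_scores = dcc_scores,
    pair_scores = pair_scores),
    class = "biomarker_report")
}

.ids <- function(labels, dimn, prefix) {
  if (!is.null(names(labels))) return(names(labels))
  if (!is.null(dimn)) return(dimn)
  paste0(prefix, seq_along(labels))
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat("Biomarker report:", length(x$biomarker_genes), "biomarker genes,",
      length(x$regulatory_dccs), "regulatory DCCs\n")
  if (nrow(x$dcc_scores)) {
    cat("Top regulatory DCCs (percent score):\n")
    print(utils::head(x$dcc_scores[, c("dcc", "score")], 10),
          row.names = FALSE)
  }
  invisible(x)
}

#' Write co-clustering and biomarker reports as CSV files
#'
#' Writes `coclusters.csv` (item, type, label), `biomarkers.csv`
#' (per-pair direction calls), `dcc_ranking.csv` and
#' `pair_ranking.csv` into `dir`.
#'
#' @param cc A `"cocluster_result"`.
#' @param report A `"biomarker_report"`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cocluster_reports <- function(cc, report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  items <- data.frame(
    item = c(.ids(cc$gene_labels, NULL, "gene"),
             .ids(cc$dcc_labels, NULL, "dcc")),
    type = rep(c("gene", "dcc"),
               c(length(cc$gene_labels), length(cc$dcc_labels))),
    label = c(cc$gene_labels, cc$dcc_labels))
  utils::write.csv(items, file.path(dir, "coclusters.csv"),
                   row.names = FALSE)
  utils::write.csv(report$direction, file.path(dir, "biomarkers.csv"),
                   row.names = FALSE)
  utils::write.csv(report$dcc_scores, file.path(dir, "dcc_ranking.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pair_scores, file.path(dir, "pair_ranking.csv"),
                   row.names = FALSE)
  invisible(dir)
}
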