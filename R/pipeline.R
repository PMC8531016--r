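#' Run the full synthetic repositioning pipeline
#'
#' Ties the stages together on one seeded synthetic study:
#' generate the compound and disease libraries, build moderated-t
#' signatures and ranked lists, extract tag sets, score every
#' compound-condition/disease pair with pooled-null permutation FDR, call
#' cross-condition inverse concordance, rank compounds by library
#' percentile against the target disease, and run the directional GSEA
#' panel for every inverse-concordant compound. When TF/PPI/kinase
#' resources are supplied, the upstream-regulator chain is run on the
#' target disease's significant genes. All results and a provenance
#' manifest (configuration, seeds, row counts, md5 digests) are written to
#' `outdir`; identical configurations produce identical outputs.
#'
#' @param cfg a [synthetic_config()] (must carry an explicit seed).
#' @param outdir output directory (created if needed).
#' @param n_top tag-set size per side (default 100).
#' @param n_perm permutation draws per pair (default 1000).
#' @param q_connectivity connectivity FDR threshold (default 0.01).
#' @param q_gsea GSEA FDR threshold (default 0.05).
#' @param deg_q DEG FDR threshold for the regulator stage (default 0.1).
#' @param gsea_exponent GSEA weighting exponent (default 1).
#' @param tf_library,kinase_library optional [gene_set_library()] objects
#'   (or GMT paths) for the regulator stage.
#' @param ppi_network optional [interaction_network()] (or two-column TSV
#'   path) for the regulator stage.
#' @return invisible list with elements `connectivity`, `concordance`,
#'   `ranking`, `gsea`, `regulators` (NULL when not run), `truth`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg, outdir, n_top = 100L, n_perm = 1000L,
                         q_connectivity = 0.01, q_gsea = 0.05, deg_q = 0.1,
                         gsea_exponent = 1,
                         tf_library = NULL, ppi_network = NULL,
                         kinase_library = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- ground_truth(cfg)

  compounds <- generate_compound_library(cfg, truth)
  diseases <- generate_disease_library(cfg, truth)

  drug_sets <- lapply(compounds, function(cc) {
    sig <- differential_signature(cc$treated, cc$control)
    signature_gene_sets(sig, n_top = n_top,
                        origin = paste(cc$compound, cc$condition, sep = "|"))
  })
  disease_ranked <- lapply(diseases, function(d) {
    ranked_list(differential_signature(d$case, d$control))
  })

  conn <- score_library(drug_sets, disease_ranked, n_perm = n_perm, seed = cfg$seed)

  cpds <- unique(conn$compound)
  n_cond <- length(unique(conn$condition))
  conc <- do.call(rbind, lapply(cpds, function(cpd) {
    do.call(rbind, lapply(unique(conn$disease), function(dis) {
      call <- concordant_inverse(conn, cpd, dis, q_threshold = q_connectivity,
                                 expected_conditions = n_cond)
      data.frame(compound = cpd, disease = dis,
                 inverse_concordant = call$inverse_concordant,
                 stringsAsFactors = FALSE)
    }))
  }))

  ranking <- rank_compounds(conn, truth$target_disease_id)

  hits <- unique(conc$compound[conc$inverse_concordant &
                                 conc$disease == truth$target_disease_id])
  gsea_tab <- NULL
  if (length(hits)) {
    gsea_tab <- do.call(rbind, lapply(hits, function(cpd) {
      key <- grep(paste0("^", cpd, "\\|"), names(drug_sets), value = TRUE)[1]
      panel <- signature_direction_panel(drug_sets[[key]], disease_ranked,
                                         exponent = gsea_exponent,
                                         n_perm = n_perm, seed = cfg$seed,
                                         q_threshold = q_gsea)
      cbind(compound = cpd, condition = sub("^[^|]*\\|", "", key), panel,
            stringsAsFactors = FALSE)
    }))
  }

  reg_tab <- NULL
  if (!is.null(tf_library) && !is.null(ppi_network) && !is.null(kinase_library)) {
    if (is.character(tf_library)) {
      sets <- read_gmt(tf_library)
      tf_library <- gene_set_library(sets, unique(c(unlist(sets), gene_universe(cfg))))
    }
    if (is.character(kinase_library)) {
      sets <- read_gmt(kinase_library)
      kinase_library <- gene_set_library(sets, unique(c(unlist(sets), gene_universe(cfg))))
    }
    if (is.character(ppi_network))
      ppi_network <- interaction_network(utils::read.delim(ppi_network, header = FALSE))
    dsig <- differential_signature(diseases[[truth$target_disease_id]]$case,
                                   diseases[[truth$target_disease_id]]$control)
    degs <- dsig$gene[!is.na(dsig$q) & dsig$q < deg_q]
    tf <- fisher_enrichment(degs, tf_library)
    top_tf <- tf$term[!is.na(tf$q) & tf$q < q_gsea]
    if (length(top_tf) < 2L) top_tf <- utils::head(tf$term, 5L)
    subnet <- expand_network(top_tf, ppi_network)
    kin <- kinase_enrichment(subnet, kinase_library)
    reg_tab <- list(tf = tf, subnetwork_nodes = igraph::V(subnet)$name, kinase = kin)
  }

  # ---- outputs -------------------------------------------------------------
  files <- character(0)
  wr <- function(obj, name) {
    path <- file.path(outdir, name)
    utils::write.csv(as.data.frame(obj), path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))
  files <- c(files, file.path(outdir, "config.yaml"))
  gt_path <- file.path(outdir, "ground_truth.tsv")
  utils::write.table(data.frame(gene = truth$effect_genes,
                                direction = unname(truth$effect_directions)),
                     gt_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, gt_path)
  wr(conn, "connectivity.csv")
  wr(conc, "concordance.csv")
  wr(ranking, "compound_ranking.csv")
  if (!is.null(gsea_tab)) wr(gsea_tab, "gsea_panel.csv")
  if (!is.null(reg_tab)) {
    wr(reg_tab$tf, "regulators_tf.csv")
    wr(reg_tab$kinase, "regulators_kinase.csv")
    writeLines(reg_tab$subnetwork_nodes, file.path(outdir, "subnetwork_nodes.txt"))
    files <- c(files, file.path(outdir, "subnetwork_nodes.txt"))
  }

  manifest <- list(
    package = "sigrev",
    version = as.character(utils::packageVersion("sigrev")),
    config = unclass(cfg),
    parameters = list(n_top = n_top, n_perm = n_perm,
                      q_connectivity = q_connectivity, q_gsea = q_gsea,
                      deg_q = deg_q, gsea_exponent = gsea_exponent),
    row_counts = list(connectivity = nrow(conn), concordance = nrow(conc),
                      ranking = nrow(ranking),
                      gsea = if (is.null(gsea_tab)) 0L else nrow(gsea_tab)),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(connectivity = conn, concordance = conc, ranking = ranking,
                 gsea = gsea_tab, regulators = reg_tab, truth = truth,
                 manifest = manifest))
}
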