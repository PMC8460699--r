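#' Construct an omics table
#'
#' A genes x patients value matrix with a declared kind. Gene and patient
#' names must be unique.
#'
#' @param values numeric matrix, genes in rows (named), patients in columns
#'   (named).
#' @param kind one of "expression", "cna", "point_mutation".
#' @return Object of class `omics_table`.
#' @export
omics_table <- function(values, kind = c("expression", "cna", "point_mutation")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_arg("`values` needs gene row names and patient column names")
  if (anyDuplicated(rownames(values))) stop_arg("gene names must be unique")
  if (anyDuplicated(colnames(values))) stop_arg("patient ids must be unique")
  structure(list(values = values, kind = kind), class = "omics_table")
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("omics table (%s): %d genes x %d patients\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Validate (or build) a pathway-definition table
#'
#' Pathway membership with oncogene/suppressor roles. Member weights are +1
#' for oncogenes and -1 for tumor suppressors.
#'
#' @param defs data.frame with columns `pathway`, `gene`, `role`
#'   (role in "oncogene"/"suppressor").
#' @return The validated data.frame with an added numeric `weight` column.
#' @export
validate_pathway_defs <- function(defs) {
  if (!is.data.frame(defs) || !all(c("pathway", "gene", "role") %in% names(defs)))
    stop_arg("pathway definitions need columns pathway, gene, role")
  if (!all(defs$role %in% c("oncogene", "suppressor")))
    stop_arg("role must be 'oncogene' or 'suppressor'")
  if (nrow(defs) == 0L) stop_arg("pathway definitions are empty")
  if (anyDuplicated(defs[c("pathway", "gene")]))
    stop_arg("duplicate pathway/gene pairs in definitions")
  defs$weight <- ifelse(defs$role == "oncogene", 1, -1)
  defs
}

#' Read pathway definitions from a TSV file
#'
#' The package ships an illustrative definition of the ten canonical
#' signalling pathways (cell cycle, Hippo, Myc, Notch, Nrf2, PI3K, RTK-RAS,
#' TGF-beta, p53, Wnt) with a small set of well-known member genes in
#' `system.file("extdata", "pathways_default.tsv", package = "wsimil")`;
#' users supply their own catalog the same way.
#'
#' @param path TSV with columns pathway, gene, role.
#' @return Validated pathway-definition data.frame (see
#'   [validate_pathway_defs()]).
#' @export
read_pathway_defs <- function(path) {
  validate_pathway_defs(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Binarize alteration calls to altered/unaltered
#'
#' Point mutations: any nonzero call is altered. Copy-number alterations use
#' discrete GISTIC-style calls in \{-2, -1, 0, 1, 2\}; under the default
#' `"nonzero"` convention any nonzero call is altered, under `"level2"` only
#' deep deletions/high amplifications (|call| >= 2) are.
#'
#' @param table an [omics_table()] of kind "cna" or "point_mutation".
#' @param convention CNA convention, `"nonzero"` or `"level2"`.
#' @return An [omics_table()] of kind "point_mutation" holding 0/1 calls.
#' @export
binarize_alterations <- function(table, convention = c("nonzero", "level2")) {
  stopifnot(inherits(table, "omics_table"))
  convention <- match.arg(convention)
  v <- table$values
  if (table$kind == "cna") {
    if (any(v != round(v)))
      stop_arg("CNA values must be discrete integer calls under this convention")
    level <- if (convention == "nonzero") 1 else 2
    out <- (abs(v) >= level) * 1L
  } else {
    out <- (v != 0) * 1L
  }
  omics_table(out, "point_mutation")
}

#' Select genes by alteration prevalence
#'
#' Keeps genes whose altered fraction reaches `min_prevalence`
#' (`>=` by default, strictly `>` when `strict = TRUE` — the convention for
#' copy-number gene selection). Output is sorted by descending prevalence,
#' ties broken by gene name.
#'
#' @param table a binarized [omics_table()] (0/1 values).
#' @param min_prevalence prevalence threshold in \[0, 1\].
#' @param strict if `TRUE`, require prevalence strictly greater than the
#'   threshold.
#' @return data.frame with columns `gene`, `prevalence` (possibly 0 rows).
#' @examples
#' m <- matrix(c(1, 0, 0, 0, 1, 1), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("p1", "p2")))
#' select_genes(omics_table(m, "point_mutation"), 0.5)
#' @export
select_genes <- function(table, min_prevalence, strict = FALSE) {
  stopifnot(inherits(table, "omics_table"))
  if (ncol(table$values) == 0L || nrow(table$values) == 0L)
    return(data.frame(gene = character(), prevalence = numeric()))
  prev <- rowMeans(table$values != 0)
  keep <- if (strict) prev > min_prevalence else prev >= min_prevalence
  genes <- names(prev)[keep]
  ord <- order(-prev[keep], genes)
  data.frame(gene = genes[ord], prevalence = unname(prev[keep][ord]))
}

#' Pathway activity scores and binary activity labels
#'
#' For each patient s and pathway i, the activity is the weighted mean over
#' the pathway's member genes of the gene's value (expression or copy-number
#' level), with weight +1 for oncogenes and -1 for tumor suppressors:
#' `v = mean_n(w_n * u_n)`. The binary label is `l = 1` exactly where
#' `v > 0` (an activity of exactly zero is inactivated). Member genes missing
#' from the table, or values that are `NA` for a patient, are dropped from
#' that mean with the member count adjusted, with a warning; a pathway with
#' no member present in the table is an error.
#'
#' @param table an [omics_table()] of kind "expression" or "cna".
#' @param defs pathway definitions (see [validate_pathway_defs()]).
#' @return Object of class `pathway_activity`: `v` and `l`
#'   (patients x pathways matrices) and `source` ("expression" or "cna").
#' @examples
#' m <- matrix(c(3, 1), 2, 1, dimnames = list(c("ONC", "SUP"), "p1"))
#' defs <- data.frame(pathway = "pw", gene = c("ONC", "SUP"),
#'                    role = c("oncogene", "suppressor"))
#' pathway_activity(omics_table(m, "expression"), defs)$v  # (3 - 1)/2 = 1
#' @export
pathway_activity <- function(table, defs) {
  stopifnot(inherits(table, "omics_table"))
  if (!table$kind %in% c("expression", "cna"))
    stop_arg("pathway activity needs an expression or cna table")
  defs <- validate_pathway_defs(defs)
  pws <- unique(defs$pathway)
  patients <- colnames(table$values)
  v <- matrix(NA_real_, length(patients), length(pws),
              dimnames = list(patients, pws))
  for (p in pws) {
    mem <- defs[defs$pathway == p, , drop = FALSE]
    present <- mem$gene %in% rownames(table$values)
    if (!any(present))
      stop_arg("pathway '", p, "' has no member gene present in the table")
    if (!all(present))
      warning(sprintf("pathway '%s': %d member gene(s) absent from the table; member count adjusted",
                      p, sum(!present)))
    mem <- mem[present, , drop = FALSE]
    u <- table$values[mem$gene, , drop = FALSE]
    wu <- mem$weight * u
    n_ok <- colSums(!is.na(u))
    if (any(is.na(u)))
      warning(sprintf("pathway '%s': NA values dropped with member count adjusted", p))
    if (any(n_ok == 0))
      stop_arg("pathway '", p, "' has a patient with no usable member value")
    v[, p] <- colSums(wu, na.rm = TRUE) / n_ok
  }
  structure(list(v = v, l = (v > 0) * 1L, source = table$kind),
            class = "pathway_activity")
}

#' @export
print.pathway_activity <- function(x, ...) {
  cat(sprintf("pathway activity (%s): %d patients x %d pathways, %.0f%% activated\n",
              x$source, nrow(x$v), ncol(x$v), 100 * mean(x$l)))
  invisible(x)
}

#' Assemble the per-task binary label table
#'
#' One binary column per prediction task. Tasks are rows of a data.frame with
#' columns `name`, `type` (one of "gene_point", "gene_cna", "pathway_expr",
#' "pathway_cna") and `target` (gene or pathway name). Per-task positive
#' counts are attached as attribute `"positives"`. If `cache_patients` is
#' given, labelled patients missing from it are reported with a warning.
#'
#' @param mutations binarized point-mutation [omics_table()] (or `NULL`).
#' @param cna binarized CNA [omics_table()] (or `NULL`).
#' @param activities_expr,activities_cna [pathway_activity()] objects (or
#'   `NULL`).
#' @param tasks task data.frame (zero rows give an empty table).
#' @param cache_patients optional character vector of patients with cached
#'   features.
#' @return data.frame with `patient_id` and one 0/1 column per task.
#' @export
make_label_table <- function(mutations = NULL, cna = NULL,
                             activities_expr = NULL, activities_cna = NULL,
                             tasks = data.frame(), cache_patients = NULL) {
  pools <- list(gene_point = mutations, gene_cna = cna,
                pathway_expr = activities_expr, pathway_cna = activities_cna)
  patients <- NULL
  for (x in pools) {
    ids <- if (inherits(x, "omics_table")) colnames(x$values)
           else if (inherits(x, "pathway_activity")) rownames(x$v) else NULL
    if (!is.null(ids)) patients <- if (is.null(patients)) ids else intersect(patients, ids)
  }
  if (is.null(patients)) patients <- character()
  out <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  if (nrow(tasks) > 0L) {
    if (!all(c("name", "type", "target") %in% names(tasks)))
      stop_arg("tasks need columns name, type, target")
    positives <- integer(nrow(tasks))
    for (k in seq_len(nrow(tasks))) {
      src <- pools[[tasks$type[k]]]
      if (is.null(src))
        stop_arg("no source table supplied for task type '", tasks$type[k], "'")
      col <- if (inherits(src, "omics_table")) {
        if (!tasks$target[k] %in% rownames(src$values))
          stop_arg("gene '", tasks$target[k], "' not in the source table")
        src$values[tasks$target[k], patients]
      } else {
        if (!tasks$target[k] %in% colnames(src$l))
          stop_arg("pathway '", tasks$target[k], "' not in the activity matrix")
        src$l[patients, tasks$target[k]]
      }
      out[[tasks$name[k]]] <- as.integer(col)
      positives[k] <- sum(col)
    }
    attr(out, "positives") <- stats::setNames(positives, tasks$name)
  }
  if (!is.null(cache_patients)) {
    missing <- setdiff(patients, cache_patients)
    if (length(missing))
      warning("patients labelled but absent from the feature cache: ",
              paste(missing, collapse = ", "))
  }
  out
}

#' Write a label table to TSV
#' @param labels data.frame from [make_label_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
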