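#' @importFrom stats optimize optim pnorm qnorm median var rbinom rnorm runif setNames
#' @importFrom utils read.csv write.csv
NULL

RELATION_TYPES <- c("mutually_exclusive", "subset_a_of_b", "subset_b_of_a", "unrelated")

#' Construct a multi-outcome meta-analysis dataset
#'
#' Bundles per-study 2x2 tables for one or more binary outcomes with the
#' structural relations between outcome pairs (mutually exclusive, subset,
#' or unrelated). All count and relation invariants are validated eagerly:
#' the analytic within-study correlation formulas are undefined when, for
#' example, a subset outcome has more events than its superset, so such
#' datasets are rejected rather than flagged.
#'
#' @param tables data.frame with columns `study_id`, `outcome_id`,
#'   `events_t`, `n_t`, `events_c`, `n_c` (events and totals in the
#'   treatment and control arm).
#' @param relations optional data.frame with columns `outcome_a`,
#'   `outcome_b`, `relation` (one of `"mutually_exclusive"`,
#'   `"subset_a_of_b"`, `"subset_b_of_a"`, `"unrelated"`). Pairs not listed
#'   are treated as unrelated.
#' @param outcome_ids optional character vector fixing the outcome order;
#'   defaults to order of first appearance in `tables`.
#' @return An object of class `meta_dataset`.
#' @export
meta_dataset <- function(tables, relations = NULL, outcome_ids = NULL) {
  tables <- validate_tables(tables)
  if (is.null(outcome_ids)) {
    outcome_ids <- unique(as.character(tables$outcome_id))
  } else {
    outcome_ids <- as.character(outcome_ids)
    extra <- setdiff(unique(tables$outcome_id), outcome_ids)
    if (length(extra) > 0L) {
      stop("tables contain outcomes absent from 'outcome_ids': ",
           paste(extra, collapse = ", "))
    }
  }
  if (length(outcome_ids) < 1L) stop("dataset must declare at least one outcome")
  relations <- validate_relations(relations, outcome_ids)
  ds <- structure(
    list(tables = tables, relations = relations, outcome_ids = outcome_ids),
    class = "meta_dataset"
  )
  check_structural_invariants(ds)
  ds
}

validate_tables <- function(tables) {
  req <- c("study_id", "outcome_id", "events_t", "n_t", "events_c", "n_c")
  missing_cols <- setdiff(req, names(tables))
  if (length(missing_cols) > 0L) {
    stop("tables are missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  tables <- as.data.frame(tables)[req]
  tables$study_id <- as.character(tables$study_id)
  tables$outcome_id <- as.character(tables$outcome_id)
  for (col in c("events_t", "n_t", "events_c", "n_c")) {
    x <- tables[[col]]
    bad <- which(!is.finite(x) | x < 0 | x != round(x))
    if (length(bad) > 0L) {
      stop(sprintf("column '%s' has a negative or non-integer count in row %d",
                   col, bad[1L]))
    }
    tables[[col]] <- as.integer(round(x))
  }
  bad <- which(tables$n_t < 1L | tables$n_c < 1L)
  if (length(bad) > 0L) {
    stop("arm total < 1 in row ", bad[1L])
  }
  bad <- which(tables$events_t > tables$n_t | tables$events_c > tables$n_c)
  if (length(bad) > 0L) {
    stop("events exceed arm total in row ", bad[1L])
  }
  key <- paste(tables$study_id, tables$outcome_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (study_id, outcome_id) pair: ",
         sub("\r", " / ", key[duplicated(key)][1L]))
  }
  rownames(tables) <- NULL
  tables
}

validate_relations <- function(relations, outcome_ids) {
  if (is.null(relations) || nrow(as.data.frame(relations)) == 0L) {
    return(data.frame(outcome_a = character(), outcome_b = character(),
                      relation = character(), stringsAsFactors = FALSE))
  }
  relations <- as.data.frame(relations)
  req <- c("outcome_a", "outcome_b", "relation")
  if (!all(req %in% names(relations))) {
    stop("relations need columns outcome_a, outcome_b, relation")
  }
  relations <- relations[req]
  relations$outcome_a <- as.character(relations$outcome_a)
  relations$outcome_b <- as.character(relations$outcome_b)
  relations$relation <- as.character(relations$relation)
  bad <- setdiff(relations$relation, RELATION_TYPES)
  if (length(bad) > 0L) {
    stop("unknown relation keyword: ", bad[1L],
         " (expected one of ", paste(RELATION_TYPES, collapse = ", "), ")")
  }
  undeclared <- setdiff(c(relations$outcome_a, relations$outcome_b), outcome_ids)
  if (length(undeclared) > 0L) {
    stop("relation references undeclared outcome: ", undeclared[1L])
  }
  if (any(relations$outcome_a == relations$outcome_b)) {
    stop("a relation must link two distinct outcomes")
  }
  key <- pair_key(relations$outcome_a, relations$outcome_b)
  if (anyDuplicated(key)) {
    stop("outcome pair declared twice in relations: ",
         gsub("\r", " / ", key[duplicated(key)][1L]))
  }
  rownames(relations) <- NULL
  relations
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Look up the declared relation for an outcome pair
#'
#' Returns the relation oriented as (a, b): a declared `subset_a_of_b`
#' flips to `subset_b_of_a` when queried in the opposite order. Pairs with
#' no declared relation are `"unrelated"`.
#'
#' @param dataset a `meta_dataset`.
#' @param a,b outcome identifiers.
#' @return One of `"mutually_exclusive"`, `"subset_a_of_b"`,
#'   `"subset_b_of_a"`, `"unrelated"`.
#' @export
get_relation <- function(dataset, a, b) {
  rel <- dataset$relations
  hit <- which(rel$outcome_a == a & rel$outcome_b == b)
  if (length(hit) == 1L) return(rel$relation[hit])
  hit <- which(rel$outcome_a == b & rel$outcome_b == a)
  if (length(hit) == 1L) {
    r <- rel$relation[hit]
    if (r == "subset_a_of_b") return("subset_b_of_a")
    if (r == "subset_b_of_a") return("subset_a_of_b")
    return(r)
  }
  "unrelated"
}

# Eager cross-table checks: subset events never exceed superset events and
# mutually exclusive events never sum past the arm total, in any study
# reporting both outcomes of a related pair.
check_structural_invariants <- function(ds) {
  rel <- ds$relations
  if (nrow(rel) == 0L) return(invisible(ds))
  tab <- ds$tables
  for (i in seq_len(nrow(rel))) {
    r <- rel$relation[i]
    if (r == "unrelated") next
    a <- rel$outcome_a[i]; b <- rel$outcome_b[i]
    ta <- tab[tab$outcome_id == a, , drop = FALSE]
    tb <- tab[tab$outcome_id == b, , drop = FALSE]
    common <- intersect(ta$study_id, tb$study_id)
    for (s in common) {
      xa <- ta[ta$study_id == s, ]
      xb <- tb[tb$study_id == s, ]
      if (xa$n_t != xb$n_t || xa$n_c != xb$n_c) {
        stop(sprintf("study '%s': arm totals differ between related outcomes '%s' and '%s'",
                     s, a, b))
      }
      if (r == "mutually_exclusive") {
        if (xa$events_t + xb$events_t > xa$n_t ||
            xa$events_c + xb$events_c > xa$n_c) {
          stop(sprintf("study '%s': mutually exclusive outcomes '%s' and '%s' have events summing past the arm total",
                       s, a, b))
        }
      } else {
        sub <- if (r == "subset_a_of_b") xa else xb
        sup <- if (r == "subset_a_of_b") xb else xa
        if (sub$events_t > sup$events_t || sub$events_c > sup$events_c) {
          stop(sprintf("study '%s': subset outcome has more events than its superset ('%s' / '%s')",
                       s, a, b))
        }
      }
    }
  }
  invisible(ds)
}

#' @export
print.meta_dataset <- function(x, ...) {
  cat("Multi-outcome meta-analysis dataset\n")
  cat(sprintf("  %d studies, %d outcomes, %d 2x2 tables\n",
              length(unique(x$tables$study_id)), length(x$outcome_ids),
              nrow(x$tables)))
  for (oid in x$outcome_ids) {
    cat(sprintf("  outcome '%s': %d reporting studies\n", oid,
                sum(x$tables$outcome_id == oid)))
  }
  if (nrow(x$relations) > 0L) {
    cat("  relations:\n")
    for (i in seq_len(nrow(x$relations))) {
      cat(sprintf("    %s ~ %s: %s\n", x$relations$outcome_a[i],
                  x$relations$outcome_b[i], x$relations$relation[i]))
    }
  }
  invisible(x)
}

#' Read a multi-outcome meta-analysis dataset from disk
#'
#' The tables file is comma-separated text with a header row and exactly the
#' six columns `study_id, outcome_id, events_t, n_t, events_c, n_c`. The
#' relations file is a small YAML config with a top-level `relations` list,
#' each entry holding `outcome_a`, `outcome_b` and `relation`, and an
#' optional top-level `outcomes` list fixing the outcome order. Outcome
#' pairs not declared default to unrelated.
#'
#' @param tables_path path to the CSV of 2x2 tables.
#' @param relations_path optional path to the YAML relations config.
#' @return A validated [meta_dataset].
#' @examples
#' tables <- system.file("extdata", "example_synthetic_tables.csv",
#'                       package = "mvbmeta")
#' relations <- system.file("extdata", "example_synthetic_relations.yaml",
#'                          package = "mvbmeta")
#' ds <- read_dataset(tables, relations)
#' eligibility_filter(ds)
#' @export
read_dataset <- function(tables_path, relations_path = NULL) {
  tables <- read.csv(tables_path, stringsAsFactors = FALSE)
  relations <- NULL
  outcome_ids <- NULL
  if (!is.null(relations_path)) {
    cfg <- yaml::read_yaml(relations_path)
    if (!is.null(cfg$outcomes)) outcome_ids <- as.character(unlist(cfg$outcomes))
    if (!is.null(cfg$relations)) {
      relations <- do.call(rbind, lapply(cfg$relations, function(r) {
        data.frame(outcome_a = as.character(r$outcome_a),
                   outcome_b = as.character(r$outcome_b),
                   relation = as.character(r$relation),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  meta_dataset(tables, relations, outcome_ids)
}

#' Write a meta-analysis dataset to disk
#'
#' Inverse of [read_dataset()]: writes the tables CSV and the YAML relations
#' config so that reading them back reproduces the dataset.
#'
#' @param dataset a `meta_dataset`.
#' @param tables_path output CSV path.
#' @param relations_path output YAML path.
#' @return `dataset`, invisibly.
#' @export
write_dataset <- function(dataset, tables_path, relations_path = NULL) {
  stopifnot(inherits(dataset, "meta_dataset"))
  write.csv(dataset$tables, tables_path, row.names = FALSE, quote = FALSE)
  if (!is.null(relations_path)) {
    cfg <- list(outcomes = as.list(dataset$outcome_ids))
    if (nrow(dataset$relations) > 0L) {
      cfg$relations <- lapply(seq_len(nrow(dataset$relations)), function(i) {
        list(outcome_a = dataset$relations$outcome_a[i],
             outcome_b = dataset$relations$outcome_b[i],
             relation = dataset$relations$relation[i])
      })
    }
    yaml::write_yaml(cfg, relations_path)
  }
  invisible(dataset)
}

#' Dataset-level eligibility filter
#'
#' An outcome is eligible when it is reported by at least `min_studies`
#' studies (default 3, the usual criterion for a meaningful random-effects
#' synthesis). The returned report carries a dataset-level attribute
#' `mvma_eligible`, true when at least two outcomes are eligible, i.e. when
#' a multivariate joint synthesis is worth attempting at all.
#'
#' @param dataset a `meta_dataset`.
#' @param min_studies minimum number of reporting studies per outcome.
#' @return data.frame with columns `outcome_id`, `n_studies_reporting`,
#'   `eligible`, `reason`; attribute `mvma_eligible` is a single logical.
#' @export
eligibility_filter <- function(dataset, min_studies = 3L) {
  stopifnot(inherits(dataset, "meta_dataset"), min_studies >= 1L)
  counts <- vapply(dataset$outcome_ids, function(oid) {
    sum(dataset$tables$outcome_id == oid)
  }, integer(1L))
  eligible <- counts >= min_studies
  rep <- data.frame(
    outcome_id = dataset$outcome_ids,
    n_studies_reporting = unname(counts),
    eligible = unname(eligible),
    reason = ifelse(eligible,
                    sprintf("reported by %d studies (>= %d)", counts, min_studies),
                    sprintf("reported by %d studies (< %d)", counts, min_studies)),
    stringsAsFactors = FALSE
  )
  rownames(rep) <- NULL
  attr(rep, "mvma_eligible") <- sum(eligible) >= 2L
  rep
}

#' Export an eligibility report as JSON
#'
#' @param report output of [eligibility_filter()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
eligibility_to_json <- function(report, path = NULL) {
  obj <- list(outcomes = report,
              mvma_eligible = isTRUE(attr(report, "mvma_eligible")))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
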