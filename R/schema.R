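#' Define a categorical dataset schema
#'
#' A schema lists the categorical variables of a station dataset in a fixed
#' canonical order, together with each variable's ordered state labels and
#' its role. Exactly one variable has role `"class"` (the fraud type in the
#' food fraud setting); the rest are features. The canonical variable order
#' and the lexicographic state order drive every downstream tie-break
#' (conditional probability table layout, spanning-tree root choice,
#' argmax ties), so a schema is deterministic across serializations.
#'
#' @param variables A data frame with columns `variable` (character), `role`
#'   (`"class"` or `"feature"`) and `states` (list column of character
#'   vectors). Row order is the canonical variable order.
#' @return A `tan_schema` object: the validated tibble with class
#'   `tan_schema`.
#' @examples
#' tan_schema(tibble::tibble(
#'   variable = c("Fraud type", "Product"),
#'   role = c("class", "feature"),
#'   states = list(c("Dilution", "Smuggling"), c("Fish", "Oils"))
#' ))
#' @export
tan_schema <- function(variables) {
  variables <- tibble::as_tibble(variables)
  stopifnot(all(c("variable", "role", "states") %in% names(variables)))
  variables <- variables[, c("variable", "role", "states")]
  if (anyDuplicated(variables$variable)) {
    rlang::abort("schema variable names must be unique")
  }
  if (!all(variables$role %in% c("class", "feature"))) {
    rlang::abort("variable roles must be \"class\" or \"feature\"")
  }
  if (sum(variables$role == "class") != 1L) {
    rlang::abort("schema must have exactly one variable with role \"class\"")
  }
  variables$states <- lapply(variables$states, function(s) {
    s <- as.character(s)
    if (anyDuplicated(s)) rlang::abort("state labels must be unique")
    if (any(!nzchar(s))) rlang::abort("state labels must be non-empty")
    s
  })
  structure(variables, class = c("tan_schema", class(tibble::tibble())))
}

#' @export
print.tan_schema <- function(x, ...) {
  cat("<tan_schema> ", nrow(x), " variables (class: ",
    class_var(x), ")\n",
    sep = ""
  )
  for (i in seq_len(nrow(x))) {
    s <- x$states[[i]]
    shown <- paste(utils::head(s, 4), collapse = ", ")
    if (length(s) > 4) shown <- paste0(shown, ", ...")
    cat(
      "  ", format(x$variable[i], width = 14), " [", x$role[i], ", ",
      length(s), " states] ", shown, "\n",
      sep = ""
    )
  }
  invisible(x)
}

# locale-independent lexicographic sort used for all state ordering
lex_sort <- function(x) sort(unique(as.character(x)), method = "radix")

#' @rdname tan_schema
#' @param schema A `tan_schema`.
#' @export
class_var <- function(schema) schema$variable[schema$role == "class"]

#' @rdname tan_schema
#' @export
feature_vars <- function(schema) schema$variable[schema$role == "feature"]

#' @rdname tan_schema
#' @param var A variable name present in `schema`.
#' @export
schema_states <- function(schema, var) {
  i <- match(var, schema$variable)
  if (is.na(i)) rlang::abort(paste0("variable not in schema: ", var))
  schema$states[[i]]
}

#' Infer a schema from observed data
#'
#' States are the lexicographically sorted distinct values of each column;
#' the caller names the class column. Columns keep the data frame's order as
#' the canonical order.
#'
#' @param data A data frame of categorical records (character columns).
#' @param class_var Name of the column holding the class variable.
#' @return A [tan_schema()].
#' @export
schema_infer <- function(data, class_var) {
  if (!class_var %in% names(data)) {
    rlang::abort(paste0("class column not found: ", class_var))
  }
  tan_schema(tibble::tibble(
    variable = names(data),
    role = ifelse(names(data) == class_var, "class", "feature"),
    states = lapply(data, function(col) lex_sort(col[!is.na(col)]))
  ))
}

#' Harmonize schemas across stations
#'
#' Stations in a federation may observe different subsets of each variable's
#' states (a station can even lack a whole fraud type). The harmonized
#' schema takes, per variable, the lexicographically ordered union of all
#' stations' states, so it is deterministic and independent of input order,
#' and is idempotent, commutative and associative.
#'
#' @param schemas A list of [tan_schema()] objects sharing variable names
#'   and roles.
#' @return A single harmonized [tan_schema()]. Variable order follows the
#'   first schema.
#' @export
harmonize_schemas <- function(schemas) {
  stopifnot(length(schemas) >= 1)
  ref <- schemas[[1]]
  for (s in schemas[-1]) {
    if (!setequal(s$variable, ref$variable)) {
      rlang::abort("schemas must share the same variable names")
    }
    m <- match(ref$variable, s$variable)
    if (!identical(s$role[m], ref$role)) {
      rlang::abort("conflicting roles for the same variable name")
    }
  }
  tan_schema(tibble::tibble(
    variable = ref$variable,
    role = ref$role,
    states = lapply(ref$variable, function(v) {
      lex_sort(unlist(lapply(schemas, schema_states, var = v)))
    })
  ))
}

#' Serialize a schema to canonical JSON
#'
#' The canonical form (fixed key order, canonical variable order, explicit
#' state lists) is what the schema fingerprint hashes, so two schemas agree
#' iff their canonical JSON agrees.
#'
#' @param schema A [tan_schema()].
#' @return A JSON string.
#' @export
schema_to_json <- function(schema) {
  payload <- list(
    format = "fedtan-schema",
    version = 1L,
    variables = lapply(seq_len(nrow(schema)), function(i) {
      list(
        variable = schema$variable[i],
        role = schema$role[i],
        states = as.list(schema$states[[i]])
      )
    })
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE))
}

#' @rdname schema_to_json
#' @param json A JSON string produced by [schema_to_json()].
#' @export
schema_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(payload$format, "fedtan-schema")) {
    rlang::abort("not a fedtan schema JSON document")
  }
  tan_schema(tibble::tibble(
    variable = vapply(payload$variables, `[[`, "", "variable"),
    role = vapply(payload$variables, `[[`, "", "role"),
    states = lapply(payload$variables, function(v) {
      unlist(v$states, use.names = FALSE)
    })
  ))
}

#' Fingerprint of a harmonized schema
#'
#' Hash (MD5) of the canonical schema JSON. Stations stamp their statistics
#' messages with this fingerprint; the coordinator rejects a message whose
#' fingerprint does not match its own harmonized schema, which catches
#' state-space mismatches before any counts are pooled.
#'
#' @param schema A [tan_schema()].
#' @return A hex digest string.
#' @export
schema_fingerprint <- function(schema) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(schema_to_json(schema), tmp, sep = "")
  unname(tools::md5sum(tmp))
}
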