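# Minimal RDF reader: N-Triples plus the Turtle subset that station
# exports use (@prefix/PREFIX directives, prefixed names, the "a" keyword,
# ";" and "," continuations, plain/typed/language-tagged literals). IRIs
# from domain ontologies are treated as opaque identifiers; no reasoning.

rdf_tokenize <- function(text) {
  n <- nchar(text)
  pos <- 1L
  tokens <- list()
  peek <- function() substr(text, pos, pos)
  at_end <- function() pos > n
  skip_ws <- function() {
    repeat {
      while (!at_end() && grepl("[ \t\r\n]", peek())) pos <<- pos + 1L
      if (!at_end() && peek() == "#") {
        while (!at_end() && peek() != "\n") pos <<- pos + 1L
      } else {
        break
      }
    }
  }
  read_until <- function(stop_char) {
    start <- pos
    esc <- FALSE
    while (!at_end()) {
      ch <- peek()
      if (esc) {
        esc <- FALSE
      } else if (ch == "\\") {
        esc <- TRUE
      } else if (ch == stop_char) {
        break
      }
      pos <<- pos + 1L
    }
    if (at_end()) rlang::abort("unterminated token in RDF input")
    out <- substr(text, start, pos - 1L)
    pos <<- pos + 1L # consume the closing char
    out
  }
  unescape <- function(x) {
    x <- gsub("\\\\n", "\n", x)
    x <- gsub("\\\\t", "\t", x)
    x <- gsub('\\\\"', '"', x)
    gsub("\\\\\\\\", "\\\\", x)
  }
  repeat {
    skip_ws()
    if (at_end()) break
    ch <- peek()
    if (ch == "<") {
      pos <- pos + 1L
      tokens[[length(tokens) + 1L]] <-
        list(type = "iri", value = read_until(">"))
    } else if (ch == '"') {
      pos <- pos + 1L
      lit <- unescape(read_until('"'))
      # optional @lang or ^^datatype suffix, both dropped
      if (!at_end() && peek() == "@") {
        pos <- pos + 1L
        while (!at_end() && grepl("[A-Za-z0-9-]", peek())) pos <- pos + 1L
      } else if (!at_end() && substr(text, pos, pos + 1L) == "^^") {
        pos <- pos + 2L
        if (peek() == "<") {
          pos <- pos + 1L
          read_until(">")
        } else {
          while (!at_end() && grepl("[^ \t\r\n;,.]", peek())) pos <- pos + 1L
        }
      }
      tokens[[length(tokens) + 1L]] <- list(type = "literal", value = lit)
    } else if (ch %in% c(".", ";", ",")) {
      pos <- pos + 1L
      tokens[[length(tokens) + 1L]] <- list(type = "punct", value = ch)
    } else {
      start <- pos
      repeat {
        if (at_end() || grepl("[ \t\r\n;,]", peek())) break
        # a "." ends the word only as statement terminator (followed by
        # whitespace or end of input); dots inside prefixed names survive
        if (peek() == ".") {
          nxt <- substr(text, pos + 1L, pos + 1L)
          if (nxt == "" || grepl("[ \t\r\n]", nxt)) break
        }
        pos <- pos + 1L
      }
      word <- substr(text, start, pos - 1L)
      if (!nzchar(word)) rlang::abort("cannot tokenize RDF input")
      tokens[[length(tokens) + 1L]] <- list(type = "word", value = word)
    }
  }
  tokens
}

# -> tibble(subject, predicate, object, object_is_literal)
rdf_parse_triples <- function(text) {
  tokens <- rdf_tokenize(text)
  prefixes <- character()
  expand <- function(tok) {
    if (tok$type == "iri") {
      return(tok$value)
    }
    if (tok$type == "word") {
      w <- tok$value
      if (w == "a") {
        return("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
      }
      m <- regmatches(w, regexec("^([A-Za-z0-9_.-]*):(.*)$", w))[[1]]
      if (length(m) == 3 && m[2] %in% names(prefixes)) {
        return(paste0(prefixes[[m[2]]], m[3]))
      }
      return(w) # blank node label or bare word, kept opaque
    }
    tok$value
  }
  subj <- character()
  pred <- character()
  obj <- character()
  lit <- logical()
  i <- 1L
  while (i <= length(tokens)) {
    tok <- tokens[[i]]
    if (tok$type == "word" &&
      tolower(tok$value) %in% c("@prefix", "prefix")) {
      label <- sub(":$", "", tokens[[i + 1L]]$value)
      prefixes[label] <- tokens[[i + 2L]]$value
      i <- i + 3L
      if (i <= length(tokens) && tokens[[i]]$type == "punct" &&
        tokens[[i]]$value == ".") {
        i <- i + 1L
      }
      next
    }
    s <- expand(tok)
    i <- i + 1L
    repeat { # predicate lists separated by ";"
      p <- expand(tokens[[i]])
      i <- i + 1L
      repeat { # object lists separated by ","
        o_tok <- tokens[[i]]
        subj <- c(subj, s)
        pred <- c(pred, p)
        obj <- c(obj, expand(o_tok))
        lit <- c(lit, o_tok$type == "literal")
        i <- i + 1L
        if (i > length(tokens)) rlang::abort("RDF statement not terminated")
        punct <- tokens[[i]]
        if (punct$type != "punct") rlang::abort("malformed RDF statement")
        i <- i + 1L
        if (punct$value != ",") break
      }
      if (punct$value != ";") break
      # tolerate "; ." trailing pattern
      if (tokens[[i]]$type == "punct" && tokens[[i]]$value == ".") {
        punct <- tokens[[i]]
        i <- i + 1L
        break
      }
    }
    if (punct$value != ".") rlang::abort("RDF statement not terminated")
  }
  tibble::tibble(
    subject = subj, predicate = pred, object = obj,
    object_is_literal = lit
  )
}

# opaque IRI -> short categorical label (fragment, else last path segment)
iri_local_name <- function(x) {
  frag <- sub("^.*#", "", x)
  ifelse(frag != x, frag, sub("^.*/", "", x))
}

#' Read a station dataset from RDF triples
#'
#' Parses an N-Triples or simple Turtle file and assembles one record per
#' subject: each schema variable's value is the object of the predicate
#' mapped to it. Literal objects contribute their lexical form; IRI objects
#' contribute their fragment (or last path segment). Subjects missing any
#' mapped predicate, holding two conflicting values for one predicate, or
#' holding a value outside the schema are rejected and counted. Predicates
#' not in the map are ignored.
#'
#' @param path RDF file path.
#' @param predicate_map Named character vector: predicate IRI -> schema
#'   variable name. Must cover every schema variable.
#' @param schema A [tan_schema()].
#' @param station_id Label for the station.
#' @return A [station_data()]; `n_rejected()` counts dropped subjects.
#' @export
read_station_rdf <- function(path, predicate_map, schema, station_id) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  predicate_map <- unlist(predicate_map)
  uncovered <- setdiff(schema$variable, predicate_map)
  if (length(uncovered) > 0) {
    rlang::abort(paste0(
      "predicate map does not cover variable(s): ",
      paste(uncovered, collapse = ", ")
    ))
  }
  triples <- rdf_parse_triples(
    paste(readLines(path, warn = FALSE), collapse = "\n")
  )
  triples <- triples[triples$predicate %in% names(predicate_map), ]
  triples$variable <- unname(predicate_map[triples$predicate])
  triples$value <- ifelse(
    triples$object_is_literal, triples$object, iri_local_name(triples$object)
  )

  subjects <- unique(triples$subject)
  rows <- vector("list", length(subjects))
  rejected <- 0L
  for (k in seq_along(subjects)) {
    sub_triples <- triples[triples$subject == subjects[k], ]
    vals <- lapply(schema$variable, function(v) {
      unique(sub_triples$value[sub_triples$variable == v])
    })
    lens <- lengths(vals)
    if (any(lens > 1)) {
      rlang::warn(paste0(
        "subject ", subjects[k], " has conflicting values; record rejected"
      ))
      rejected <- rejected + 1L
    } else if (any(lens == 0)) {
      rejected <- rejected + 1L
    } else {
      values <- unlist(vals)
      in_schema <- mapply(
        function(v, val) val %in% schema_states(schema, v),
        schema$variable, values
      )
      if (all(in_schema)) {
        rows[[k]] <- stats::setNames(as.list(values), schema$variable)
      } else {
        rlang::warn(paste0(
          "subject ", subjects[k],
          " has value(s) outside the schema; record rejected"
        ))
        rejected <- rejected + 1L
      }
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  records <- if (length(rows) == 0) {
    as.data.frame(
      stats::setNames(rep(list(character()), nrow(schema)), schema$variable)
    )
  } else {
    dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  }
  station_data(records, schema, station_id, n_rejected = rejected)
}

#' Write a station dataset as N-Triples
#'
#' Emits one subject IRI per record with one triple per variable, using the
#' supplied predicate map. Values are written as plain literals. The output
#' round-trips through [read_station_rdf()].
#'
#' @param data A [station_data()].
#' @param path Output file path.
#' @param predicate_map Named character vector: predicate IRI -> variable
#'   name (as in [read_station_rdf()]).
#' @param base_iri Prefix for generated record subject IRIs.
#' @return `path`, invisibly.
#' @export
write_station_ntriples <- function(data, path, predicate_map,
                                   base_iri = "http://example.org/record/") {
  predicate_map <- unlist(predicate_map)
  schema <- schema_of(data)
  esc <- function(x) {
    x <- gsub("\\\\", "\\\\\\\\", x)
    gsub('"', '\\\\"', x)
  }
  lines <- character()
  for (i in seq_len(nrow(data))) {
    subj <- paste0("<", base_iri, i, ">")
    for (v in schema$variable) {
      pred <- names(predicate_map)[predicate_map == v][1]
      lines <- c(lines, paste0(
        subj, " <", pred, '> "', esc(data[[v]][i]), '" .'
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
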