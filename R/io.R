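#' @name io_formats
#' @title File formats
#' @description
#' Network topologies are read from SIF (simple interaction format) and TGF
#' (trivial graph format) files; observations from a whitespace-separated
#' matrix with variables as rows and samples as columns (use
#' `transpose = TRUE` for the other orientation); discretisation
#' instructions from a small JSON document. All readers accept a file path
#' or literal text.
NULL

# file path, single string with newlines, or a character vector of lines
as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

tokenize <- function(line) {
  toks <- strsplit(trimws(line), "[ \t]+")[[1]]
  toks[nzchar(toks)]
}

#' Read a SIF topology
#'
#' Each line is `source <relation> target1 [target2 ...]`, yielding edges
#' `source -> target_i`; the relation token is read and ignored. A line with
#' a single token declares an isolated node; blank lines are skipped.
#'
#' @param x file path or SIF text.
#' @return a [cbn_topology].
#' @export
read_sif <- function(x) {
  lines <- as_lines(x)
  nodes <- character(0)
  edges <- NULL
  for (i in seq_along(lines)) {
    toks <- tokenize(lines[i])
    if (!length(toks)) next
    if (length(toks) == 1L) {
      nodes <- union(nodes, toks)
    } else if (length(toks) == 2L) {
      stop("SIF line ", i, ": source and relation but no target")
    } else {
      src <- toks[1L]
      tgts <- toks[-(1:2)]
      nodes <- union(nodes, c(src, tgts))
      edges <- rbind(edges, cbind(src, tgts))
    }
  }
  if (!length(nodes)) stop("no data: empty SIF input")
  cbn_topology(nodes, edges)
}

#' Write a SIF topology
#'
#' @param t a [cbn_topology].
#' @param file optional path; when omitted the text is returned.
#' @return the SIF text, invisibly when writing to a file.
#' @export
write_sif <- function(t, file = NULL) {
  stopifnot(inherits(t, "cbn_topology"))
  lines <- character(0)
  if (nrow(t$edges)) {
    lines <- paste(t$edges[, 1L], "r", t$edges[, 2L])
  }
  isolated <- setdiff(t$nodes, c(t$edges))
  lines <- c(lines, isolated)
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(lines, file)
  invisible(txt)
}

#' Read a TGF topology
#'
#' Node section (`id [label]` per line), a `#` separator, then an edge
#' section (`fromId toId` per line). A node's name is its label when
#' present, otherwise the id itself.
#'
#' @param x file path or TGF text.
#' @return a [cbn_topology].
#' @export
read_tgf <- function(x) {
  lines <- as_lines(x)
  sep <- which(vapply(lines, function(l) trimws(l) == "#", logical(1)))
  if (!length(sep)) stop("TGF input has no '#' separator")
  sep <- sep[1L]
  ids <- character(0); names_by_id <- character(0)
  for (i in seq_len(sep - 1L)) {
    toks <- tokenize(lines[i])
    if (!length(toks)) next
    id <- toks[1L]
    if (id %in% ids) stop("TGF line ", i, ": duplicate node id ", id)
    nm <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else id
    ids <- c(ids, id)
    names_by_id <- c(names_by_id, stats::setNames(nm, id))
  }
  if (!length(ids)) stop("no data: TGF input declares no nodes")
  edges <- NULL
  for (i in seq(sep + 1L, length.out = max(0L, length(lines) - sep))) {
    toks <- tokenize(lines[i])
    if (!length(toks)) next
    if (length(toks) != 2L) stop("TGF line ", i, ": expected 'fromId toId'")
    for (id in toks) {
      if (!id %in% ids) stop("TGF line ", i, ": undeclared node ", id)
    }
    edges <- rbind(edges, names_by_id[toks])
  }
  cbn_topology(unname(names_by_id), edges)
}

#' Write a TGF topology
#'
#' @param t a [cbn_topology].
#' @param file optional path; when omitted the text is returned.
#' @return the TGF text, invisibly when writing to a file.
#' @export
write_tgf <- function(t, file = NULL) {
  stopifnot(inherits(t, "cbn_topology"))
  id <- stats::setNames(seq_along(t$nodes), t$nodes)
  lines <- c(paste(id, t$nodes), "#")
  if (nrow(t$edges)) {
    lines <- c(lines, paste(id[t$edges[, 1L]], id[t$edges[, 2L]]))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(lines, file)
  invisible(txt)
}

#' Read an observation matrix
#'
#' Whitespace-separated matrix with variables as rows and samples as
#' columns: the first row holds sample identifiers (an optional leading
#' corner label is accepted and ignored) and the first column variable
#' names. The tokens `NA`, `na`, `nan` (any case) mark missing entries.
#'
#' @param x file path or matrix text.
#' @param transpose set `TRUE` when the file stores samples as rows and
#'   variables as columns instead.
#' @return numeric matrix (variables x samples) with `NA` for missing
#'   entries; `rownames` are variable names and `colnames` sample ids.
#' @export
read_data_matrix <- function(x, transpose = FALSE) {
  lines <- as_lines(x)
  rows <- lapply(lines, tokenize)
  rows <- rows[lengths(rows) > 0L]
  if (length(rows) < 2L) stop("no data: need a header row and one data row")
  body <- rows[-1L]
  widths <- lengths(body)
  if (length(unique(widths)) != 1L) {
    stop("ragged rows: row ", which(widths != widths[1L])[1L] + 1L,
         " has ", widths[widths != widths[1L]][1L], " fields, expected ",
         widths[1L])
  }
  m <- widths[1L] - 1L
  if (m < 1L) stop("no data: rows carry no sample values")
  header <- rows[[1L]]
  if (length(header) == m + 1L) header <- header[-1L]  # corner label
  if (length(header) != m) {
    stop("header row has ", length(header), " sample ids, expected ", m)
  }
  if (anyDuplicated(header)) stop("duplicate sample identifier(s)")
  vars <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(vars)) {
    stop("duplicate variable name(s): ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = length(vars), ncol = m,
                dimnames = list(vars, header))
  for (i in seq_along(body)) {
    toks <- body[[i]][-1L]
    miss <- tolower(toks) %in% c("na", "nan")
    vals <- suppressWarnings(as.numeric(toks))
    bad <- which(!miss & is.na(vals))
    if (length(bad)) {
      stop("non-numeric value '", toks[bad[1L]], "' for variable ", vars[i],
           ", sample ", header[bad[1L]])
    }
    vals[miss] <- NA_real_
    out[i, ] <- vals
  }
  if (transpose) out <- t(out)
  out
}

#' Write an observation matrix
#'
#' Inverse of [read_data_matrix()]: values and missing (`NA`) positions
#' round-trip exactly.
#'
#' @param m numeric matrix with row and column names.
#' @param file optional path; when omitted the text is returned.
#' @export
write_data_matrix <- function(m, file = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  fmt <- function(v) ifelse(is.na(v), "NA", format(v, digits = 15,
                                                   scientific = FALSE,
                                                   trim = TRUE))
  lines <- c(paste(colnames(m), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t")
             }, character(1)))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(lines, file)
  invisible(txt)
}

DISC_METHODS <- c("ceil", "floor", "round", "arithmetic_mean",
                  "harmonic_mean", "median", "z_score", "fixed_threshold",
                  "bracket_medians", "pearson_tukey", "none")

check_disc_entry <- function(e, where) {
  method <- e$method
  if (is.null(method) || !method %in% DISC_METHODS) {
    stop("unknown discretisation method ",
         if (is.null(method)) "(missing)" else paste0("'", method, "'"),
         " for ", where)
  }
  if (method == "fixed_threshold" && !is.numeric(e$threshold)) {
    stop("method 'fixed_threshold' for ", where, " requires a 'threshold'")
  }
  if (method == "bracket_medians") {
    b <- e$buckets
    if (!is.numeric(b) || length(b) != 1L || b < 2 || b != floor(b)) {
      stop("method 'bracket_medians' for ", where,
           " requires an integer 'buckets' >= 2")
    }
  }
  e[intersect(names(e), c("method", "threshold", "buckets"))]
}

#' Read a JSON discretisation specification
#'
#' Schema:
#' \preformatted{{"default": {"method": str, ...},
#'  "variables": [{"name": str, "method": str,
#'                 "threshold": num?, "buckets": int?}]}}
#' `method` is one of ceil, floor, round, arithmetic_mean, harmonic_mean,
#' median, z_score, fixed_threshold, bracket_medians, pearson_tukey, none.
#' The optional `default` applies to every variable without its own entry.
#'
#' @param x file path or JSON text.
#' @return an object of class `cbn_disc_spec`: list with `default` (or
#'   `NULL`) and `variables`, a named list of per-variable method entries.
#' @export
read_discretisation_spec <- function(x) {
  txt <- if (length(x) == 1L && !grepl("{", x, fixed = TRUE) &&
             file.exists(x)) x else paste(x, collapse = "\n")
  spec <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  out <- list(default = NULL, variables = list())
  if (!is.null(spec$default)) {
    out$default <- check_disc_entry(spec$default, "the default entry")
  }
  for (e in spec$variables) {
    nm <- e$name
    if (is.null(nm) || !nzchar(nm)) stop("variable entry without a 'name'")
    if (nm %in% names(out$variables)) stop("duplicate entry for variable ", nm)
    out$variables[[nm]] <- check_disc_entry(e, paste("variable", nm))
  }
  structure(out, class = "cbn_disc_spec")
}

#' Print the fitted network parameters
#'
#' Writes one block per node: a `[child | parent1 parent2 ...]` header
#' followed by one line per (parent configuration, child state) pair,
#' parent configurations enumerated in row-major order over the parents'
#' state spaces (last parent varying fastest) and probabilities with six
#' decimal places. Output is byte-stable for a fixed network, and
#' [read_parameters()] parses it back.
#'
#' @param n a [cbn] network (or fit).
#' @param file optional path; when omitted the text is returned.
#' @export
write_parameters <- function(n, file = NULL) {
  n <- as_cbn(n)
  blocks <- character(0)
  for (v in n$topology$nodes) {
    ps <- n$parents[[v]]
    header <- if (length(ps)) paste0("[", v, " | ", paste(ps, collapse = " "),
                                     "]") else paste0("[", v, "]")
    k <- nstates(n, v)
    cpt <- n$cpts[[v]]
    lines <- character(0)
    if (!length(ps)) {
      for (s in seq_len(k)) {
        lines <- c(lines, sprintf("%d %.6f", s - 1L, cpt[s]))
      }
    } else {
      kp <- nstates(n, ps)
      # row-major over parents: last parent varies fastest
      cfgs <- as.matrix(rev(expand.grid(rev(lapply(kp, function(x)
        0:(x - 1L))))))
      colnames(cfgs) <- ps
      m <- matrix(cpt, nrow = k)  # columns: first parent fastest
      for (r in seq_len(nrow(cfgs))) {
        col <- 1 + sum(cfgs[r, ] * c(1, cumprod(kp))[seq_along(ps)])
        for (s in seq_len(k)) {
          lines <- c(lines, sprintf("%s %d %.6f",
                                    paste(cfgs[r, ], collapse = " "),
                                    s - 1L, m[s, col]))
        }
      }
    }
    blocks <- c(blocks, header, lines, "")
  }
  txt <- paste0(paste(blocks, collapse = "\n"))
  if (is.null(file)) return(txt)
  writeLines(blocks, file)
  invisible(txt)
}

#' Parse parameter tables written by [write_parameters()]
#'
#' @param x file path or parameter text.
#' @return named list of CPT arrays (child dimension first, parents in the
#'   header's order).
#' @export
read_parameters <- function(x) {
  lines <- as_lines(x)
  out <- list()
  cur <- NULL; parents <- NULL; rows <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    np <- length(parents)
    states <- rows[, np + 1L]
    k <- max(states) + 1L
    kp <- if (np) vapply(seq_len(np), function(j) max(rows[, j]) + 1L,
                         numeric(1)) else numeric(0)
    a <- array(NA_real_, dim = c(k, kp))
    for (r in seq_len(nrow(rows))) {
      idx <- 1 + rows[r, np + 1L]
      if (np) {
        idx <- idx + sum(rows[r, seq_len(np)] * k *
                           c(1, cumprod(kp))[seq_len(np)])
      }
      a[idx] <- rows[r, np + 2L]
    }
    dn <- c(list(as.character(0:(k - 1L))),
            lapply(kp, function(x) as.character(0:(x - 1L))))
    dimnames(a) <- stats::setNames(dn, c(cur, parents))
    out[[cur]] <<- a
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "[")) {
      flush()
      hdr <- sub("^\\[", "", sub("\\]$", "", ln))
      parts <- strsplit(hdr, "\\|")[[1]]
      cur <- trimws(parts[1L])
      parents <- if (length(parts) > 1L) tokenize(parts[2L]) else character(0)
      rows <- NULL
    } else {
      vals <- as.numeric(tokenize(ln))
      if (length(vals) != length(parents) + 2L) {
        stop("malformed parameter line: ", ln)
      }
      rows <- rbind(rows, vals)
    }
  }
  flush()
  out
}
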