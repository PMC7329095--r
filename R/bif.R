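# BIF (Bayesian Interchange Format) input/output, covering the dialect used
# by the Bayesian Network Repository: block and line comments, `property`
# clauses (ignored with a warning), `table` clauses for unconditional
# distributions and parenthesised parent-label rows for conditional ones.

#' Read a Bayesian network from a BIF file
#'
#' @param path Path to a BIF file.
#' @return A `bn` object; variable order follows the file.
#' @seealso [write_bif()]
#' @export
read_bif <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  txt <- paste(txt, collapse = "\n")
  txt <- gsub("(?s)/\\*.*?\\*/", " ", txt, perl = TRUE)  # block comments
  txt <- gsub("//[^\n]*", " ", txt, perl = TRUE)      # line comments

  blocks <- bif_blocks(txt)
  levels <- list(); parents <- list(); cpts_raw <- list()

  for (b in blocks) {
    if (b$kind == "network") next
    if (b$kind == "variable") {
      vb <- bif_parse_variable(b)
      levels[[vb$name]] <- vb$levels
    } else if (b$kind == "probability") {
      pb <- bif_parse_probability(b, levels)
      parents[[pb$child]] <- pb$parents
      cpts_raw[[pb$child]] <- pb$cpt
    }
  }
  if (length(levels) == 0L) stop("no 'variable' blocks found in ", path,
                                 call. = FALSE)
  missing_p <- setdiff(names(levels), names(cpts_raw))
  if (length(missing_p) > 0L) {
    stop("no probability block for variable(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  bn_network(levels, parents[names(levels)], cpts_raw[names(levels)])
}

# Split BIF text into top-level blocks via brace matching.
bif_blocks <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  opens <- which(chars == "{")
  closes <- which(chars == "}")
  depth <- integer(length(chars))
  d <- 0L
  blocks <- list()
  start <- NULL
  header_from <- 1L
  for (i in seq_along(chars)) {
    if (chars[i] == "{") {
      d <- d + 1L
      if (d == 1L) start <- i
    } else if (chars[i] == "}") {
      if (d == 0L) {
        stop(sprintf("BIF parse failure near character %d: unbalanced '}'", i),
             call. = FALSE)
      }
      d <- d - 1L
      if (d == 0L) {
        header <- trimws(substr(txt, header_from, start - 1L))
        body <- substr(txt, start + 1L, i - 1L)
        kind <- sub("^([a-zA-Z]+).*", "\\1", header)
        blocks[[length(blocks) + 1L]] <-
          list(kind = tolower(kind), header = header, body = body)
        header_from <- i + 1L
      }
    }
  }
  if (d != 0L) stop("BIF parse failure: unbalanced '{'", call. = FALSE)
  blocks
}

bif_parse_variable <- function(b) {
  name <- sub("^variable\\s+(\\S+).*", "\\1", b$header)
  m <- regmatches(b$body,
                  regexec("type\\s+discrete\\s*\\[\\s*(\\d+)\\s*\\]\\s*\\{([^}]*)\\}",
                          b$body))[[1L]]
  if (length(m) == 0L) {
    stop("BIF parse failure in variable '", name,
         "': no discrete type clause", call. = FALSE)
  }
  labs <- trimws(strsplit(m[3L], ",", fixed = TRUE)[[1L]])
  labs <- labs[nzchar(labs)]
  if (length(labs) != as.integer(m[2L])) {
    stop("variable '", name, "' declares ", m[2L], " categories but lists ",
         length(labs), call. = FALSE)
  }
  if (grepl("property", b$body)) {
    warning("ignoring 'property' clause(s) in variable '", name, "'",
            call. = FALSE)
  }
  list(name = name, levels = labs)
}

bif_parse_probability <- function(b, levels) {
  hd <- sub("^probability\\s*\\(([^)]*)\\).*", "\\1", b$header)
  parts <- strsplit(hd, "|", fixed = TRUE)[[1L]]
  child <- trimws(parts[1L])
  pa <- if (length(parts) > 1L) {
    p <- trimws(strsplit(parts[2L], ",", fixed = TRUE)[[1L]])
    p[nzchar(p)]
  } else character()
  if (is.null(levels[[child]])) {
    stop("probability block for undeclared variable '", child, "'",
         call. = FALSE)
  }
  for (v in pa) if (is.null(levels[[v]])) {
    stop("probability block of '", child, "' conditions on undeclared '", v,
         "'", call. = FALSE)
  }
  card <- length(levels[[child]])
  pacards <- vapply(levels[pa], length, integer(1))
  ncfg <- prod(pacards)
  cpt <- matrix(NA_real_, nrow = ncfg, ncol = card)
  seen <- logical(ncfg)

  stmts <- strsplit(b$body, ";", fixed = TRUE)[[1L]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  for (s in stmts) {
    if (grepl("^property", s)) {
      warning("ignoring 'property' clause in probability block of '", child,
              "'", call. = FALSE)
      next
    }
    if (grepl("^table", s)) {
      vals <- bif_numbers(sub("^table", "", s), child)
      if (length(pa) == 0L) {
        if (length(vals) != card) {
          stop("table of '", child, "' has ", length(vals),
               " values, expected ", card, call. = FALSE)
        }
        cpt[1L, ] <- vals
        seen[1L] <- TRUE
      } else {
        # flat table with parents: child categories vary fastest
        if (length(vals) != card * ncfg) {
          stop("table of '", child, "' has ", length(vals),
               " values, expected ", card * ncfg, call. = FALSE)
        }
        cpt[] <- matrix(vals, nrow = ncfg, byrow = TRUE)
        seen[] <- TRUE
      }
    } else if (grepl("^\\(", s)) {
      m <- regmatches(s, regexec("^\\(([^)]*)\\)(.*)$", s))[[1L]]
      labs <- trimws(strsplit(m[2L], ",", fixed = TRUE)[[1L]])
      if (length(labs) != length(pa)) {
        stop("row of '", child, "' lists ", length(labs),
             " parent labels, expected ", length(pa), call. = FALSE)
      }
      idx <- mapply(function(l, v) match(l, levels[[v]]), labs, pa)
      if (anyNA(idx)) {
        stop("row of '", child, "' uses unknown parent category: ", m[2L],
             call. = FALSE)
      }
      g <- cpt_config_index(as.integer(idx), pacards)
      vals <- bif_numbers(m[3L], child)
      if (length(vals) != card) {
        stop("row of '", child, "' has ", length(vals), " values, expected ",
             card, call. = FALSE)
      }
      if (seen[g]) {
        stop("duplicate parent configuration (", m[2L], ") for '", child, "'",
             call. = FALSE)
      }
      cpt[g, ] <- vals
      seen[g] <- TRUE
    } else {
      warning("ignoring unrecognised clause in probability block of '",
              child, "': ", substr(s, 1L, 40L), call. = FALSE)
    }
  }
  if (!all(seen)) {
    stop("probability block of '", child, "' misses ", sum(!seen),
         " parent configuration(s)", call. = FALSE)
  }
  list(child = child, parents = pa, cpt = cpt)
}

bif_numbers <- function(s, child) {
  vals <- suppressWarnings(as.numeric(trimws(
    strsplit(s, ",", fixed = TRUE)[[1L]])))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop("no numeric values in probability row of '", child, "'",
         call. = FALSE)
  }
  vals
}

#' Write a Bayesian network to a BIF file
#'
#' Emits the repository dialect: `table` clauses for parent-free variables
#' and one parenthesised label row per parent configuration otherwise.
#' Re-reading the file with [read_bif()] yields a structurally identical
#' network.
#'
#' @param bn A `bn` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bif <- function(bn, path) {
  stopifnot(inherits(bn, "bn"))
  cards <- vapply(bn$levels, length, integer(1))
  out <- c("network exported {", "}")
  for (v in bn$nodes) {
    out <- c(out,
             sprintf("variable %s {", v),
             sprintf("  type discrete [ %d ] { %s };", cards[[v]],
                     paste(bn$levels[[v]], collapse = ", ")),
             "}")
  }
  fmt <- function(p) paste(formatC(p, digits = 10, format = "g"),
                           collapse = ", ")
  for (v in bn$nodes) {
    pa <- bn$parents[[v]]
    tab <- bn$cpts[[v]]
    if (length(pa) == 0L) {
      out <- c(out,
               sprintf("probability ( %s ) {", v),
               sprintf("  table %s;", fmt(tab[1L, ])),
               "}")
    } else {
      out <- c(out, sprintf("probability ( %s | %s ) {", v,
                            paste(pa, collapse = ", ")))
      pacards <- cards[pa]
      grid <- expand.grid(lapply(pacards, seq_len), KEEP.OUT.ATTRS = FALSE)
      for (g in seq_len(nrow(tab))) {
        idx <- as.integer(grid[g, ])
        labs <- mapply(function(i, p) bn$levels[[p]][i], idx, pa)
        out <- c(out, sprintf("  ( %s ) %s;", paste(labs, collapse = ", "),
                              fmt(tab[g, ])))
      }
      out <- c(out, "}")
    }
  }
  ok <- tryCatch({
    writeLines(out, path)
    TRUE
  }, error = function(e) {
    stop("cannot write BIF file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}
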