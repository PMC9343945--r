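#' Model assembly container
#'
#' An `hbm_assembly` holds one solver keyword-deck model: the node table,
#' element tables (solid / shell / discrete), part definitions, named scalar
#' parameters, the logical include structure, and any keyword cards the
#' reader does not interpret (kept verbatim so material or contact cards
#' pass through untouched).  Units are mm-ms-kg: coordinates in mm,
#' densities in kg/mm^3.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (and optionally
#'   `include`, the logical file unit the node came from).
#' @param solids data.frame with `id`, `part`, `n1`..`n8`.
#' @param shells data.frame with `id`, `part`, `n1`..`n4`, optional
#'   `thickness` (mm).
#' @param discretes data.frame with `id`, `part`, `n1`, `n2`.
#' @param parts data.frame with `id`, `name`, `region`, `material`,
#'   `density` (kg/mm^3).
#' @param parameters named numeric vector (or list) of deck parameters.
#' @param includes data.frame with `name` and `role`
#'   (`nodes` | `region-definition` | `control`).
#' @param extra list of unrecognized keyword blocks, each a list with
#'   `keyword`, `lines` (verbatim text), `include`.
#' @param validate run the invariant checks (unique node ids, resolvable
#'   element references, finite coordinates).
#' @return An object of class `hbm_assembly`.
#' @export
hbm_assembly <- function(nodes = empty_nodes(), solids = empty_solids(),
                         shells = empty_shells(), discretes = empty_discretes(),
                         parts = empty_parts(), parameters = numeric(),
                         includes = data.frame(name = character(),
                                               role = character()),
                         extra = list(), validate = TRUE) {
  nodes <- as.data.frame(nodes)
  if (is.null(nodes$include)) nodes$include <- NA_character_
  for (nm in c("solids", "shells", "discretes", "parts")) {
    tab <- as.data.frame(get(nm))
    if (nrow(tab) && is.null(tab$include)) tab$include <- NA_character_
    assign(nm, tab)
  }
  if (nrow(shells) && is.null(shells$thickness)) shells$thickness <- NA_real_
  x <- structure(list(nodes = nodes, solids = solids, shells = shells,
                      discretes = discretes, parts = parts,
                      parameters = unlist(parameters),
                      includes = includes, extra = extra),
                 class = "hbm_assembly")
  if (validate) validate_assembly(x)
  x
}

empty_nodes <- function() data.frame(id = integer(), x = numeric(),
                                     y = numeric(), z = numeric())
empty_solids <- function() {
  d <- data.frame(id = integer(), part = integer())
  for (k in 1:8) d[[paste0("n", k)]] <- integer()
  d
}
empty_shells <- function() {
  d <- data.frame(id = integer(), part = integer())
  for (k in 1:4) d[[paste0("n", k)]] <- integer()
  d$thickness <- numeric()
  d
}
empty_discretes <- function() data.frame(id = integer(), part = integer(),
                                         n1 = integer(), n2 = integer())
empty_parts <- function() data.frame(id = integer(), name = character(),
                                     region = character(),
                                     material = character(),
                                     density = numeric())

#' Validate assembly invariants
#'
#' Checks node-id uniqueness, that every element references existing nodes
#' and an existing part, and that all coordinates are finite.
#'
#' @param x `hbm_assembly`.
#' @return `x`, invisibly; stops with a descriptive error on violation.
#' @export
validate_assembly <- function(x) {
  dup <- x$nodes$id[duplicated(x$nodes$id)]
  if (length(dup))
    stop("duplicate node id(s): ", paste(unique(dup), collapse = ", "))
  if (nrow(x$nodes) && !all(is.finite(as.matrix(x$nodes[c("x", "y", "z")]))))
    stop("non-finite node coordinates")
  ids <- x$nodes$id
  pids <- x$parts$id
  check_elems <- function(tab, ncols, what) {
    if (!nrow(tab)) return()
    ref <- unlist(tab[paste0("n", seq_len(ncols))], use.names = FALSE)
    bad <- setdiff(unique(ref), ids)
    if (length(bad))
      stop(what, " reference missing node id(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    badp <- setdiff(unique(tab$part), pids)
    if (length(badp))
      stop(what, " reference missing part id(s): ",
           paste(badp, collapse = ", "))
  }
  check_elems(x$solids, 8, "solid elements")
  check_elems(x$shells, 4, "shell elements")
  check_elems(x$discretes, 2, "discrete elements")
  invisible(x)
}

#' @export
print.hbm_assembly <- function(x, ...) {
  cat("Keyword-deck model assembly (mm-ms-kg)\n")
  cat(sprintf("  nodes: %d   solids: %d   shells: %d   discretes: %d\n",
              nrow(x$nodes), nrow(x$solids), nrow(x$shells),
              nrow(x$discretes)))
  cat(sprintf("  parts: %d   parameters: %d   opaque card blocks: %d\n",
              nrow(x$parts), length(x$parameters), length(x$extra)))
  if (nrow(x$includes))
    cat("  includes:", paste(sprintf("%s [%s]", x$includes$name,
                                     x$includes$role), collapse = ", "), "\n")
  invisible(x)
}

SUPPORTED_KEYWORDS <- c("*KEYWORD", "*END", "*NODE", "*ELEMENT_SOLID",
                        "*ELEMENT_SHELL", "*ELEMENT_DISCRETE", "*PART",
                        "*PARAMETER", "*INCLUDE")

fw_fields <- function(line, widths) {
  # pad so trailing blank fields decode as absent
  line <- paste0(line, strrep(" ", max(0, sum(widths) - nchar(line))))
  starts <- cumsum(c(1, widths[-length(widths)]))
  vapply(seq_along(widths),
         function(i) substr(line, starts[i], starts[i] + widths[i] - 1L),
         character(1))
}

parse_numeric_fields <- function(line, widths, lineno) {
  decode <- function(toks) {
    toks <- toks[seq_len(min(length(toks), length(widths)))]
    vals <- suppressWarnings(as.numeric(toks))
    bad <- which(!is.na(toks) & nzchar(toks) & is.na(vals))
    if (length(bad)) return(toks[bad[1]])
    vals[!nzchar(toks)] <- NA_real_
    length(vals) <- length(widths)
    vals
  }
  if (grepl(",", line, fixed = TRUE)) {
    res <- decode(trimws(strsplit(line, ",", fixed = TRUE)[[1]]))
  } else {
    # strict fixed-width slicing first; free whitespace layout as fallback
    res <- decode(trimws(fw_fields(line, widths)))
    if (is.character(res)) {
      toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
      alt <- decode(toks)
      if (!is.character(alt)) res <- alt
    }
  }
  if (is.character(res))
    stop(sprintf("malformed numeric field '%s' at line %d", res, lineno))
  res
}

is_comment <- function(line) startsWith(line, "$")

#' Parse one keyword file
#'
#' Reads a solver keyword file in either the fixed-width dialect (8-character
#' integer fields, 16-character floats on `*NODE`) or the comma-separated
#' dialect; the dialect is detected per line, so mixed files parse too.
#' Recognized cards are `*NODE`, `*ELEMENT_SOLID`, `*ELEMENT_SHELL`,
#' `*ELEMENT_DISCRETE`, `*PART`, `*PARAMETER`, `*INCLUDE`, `*KEYWORD` and
#' `*END`; any other card is preserved verbatim as an opaque block and
#' re-emitted unchanged on write.
#'
#' Part cards may carry a metadata comment line directly after the title,
#' `$HBMFORGE region=<tag> density=<kg/mm3>`, which populates the region tag
#' and density columns of the part table; plain decks simply leave them NA.
#'
#' @param input a file path, a connection, or a character vector of lines.
#' @param name logical include-unit name recorded as provenance on every
#'   entity parsed from this file.
#' @return An `hbm_assembly` fragment.  Unresolved `*INCLUDE` references are
#'   recorded by name in the `includes` table with role `"unresolved"`.
#' @export
parse_keyword_file <- function(input, name = "main") {
  lines <- if (is.character(input) && length(input) == 1 &&
               !grepl("\n", input) && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else if (inherits(input, "connection")) {
    readLines(input, warn = FALSE)
  } else {
    as.character(input)
  }

  nodes <- list(); solids <- list(); shells <- list(); discretes <- list()
  parts <- list(); params <- numeric(); inc_names <- character()
  extra <- list()

  i <- 1L; n <- length(lines)
  while (i <= n) {
    line <- lines[[i]]
    if (!startsWith(line, "*")) { i <- i + 1L; next }
    kw <- toupper(trimws(strsplit(line, " ")[[1]][1]))
    block_end <- i + 1L
    while (block_end <= n && !startsWith(lines[[block_end]], "*"))
      block_end <- block_end + 1L
    body_idx <- seq.int(i + 1L, length.out = max(0L, block_end - i - 1L))
    body <- lines[body_idx]
    data_idx <- body_idx[!is_comment(body) & nzchar(trimws(body))]

    if (kw == "*NODE") {
      for (j in data_idx) {
        v <- parse_numeric_fields(lines[[j]], c(8, 16, 16, 16), j)
        if (is.na(v[1])) stop(sprintf("missing node id at line %d", j))
        nodes[[length(nodes) + 1L]] <-
          c(v[1], ifelse(is.na(v[2:4]), 0, v[2:4]))
      }
    } else if (kw %in% c("*ELEMENT_SOLID", "*ELEMENT_SHELL",
                         "*ELEMENT_DISCRETE")) {
      nfield <- switch(kw, "*ELEMENT_SOLID" = 10L, "*ELEMENT_SHELL" = 7L,
                       "*ELEMENT_DISCRETE" = 4L)
      for (j in data_idx) {
        v <- parse_numeric_fields(lines[[j]], rep(8, nfield), j)
        if (kw == "*ELEMENT_SOLID") {
          solids[[length(solids) + 1L]] <- v[1:10]
        } else if (kw == "*ELEMENT_SHELL") {
          shells[[length(shells) + 1L]] <- v[1:7]
        } else {
          discretes[[length(discretes) + 1L]] <- v[1:4]
        }
      }
    } else if (kw == "*PART") {
      # card structure: title line, optional $HBMFORGE metadata, data line
      title <- NA_character_; region <- NA_character_; dens <- NA_real_
      dataline <- NA_integer_
      for (j in body_idx) {
        bl <- lines[[j]]
        if (is_comment(bl)) {
          if (grepl("^\\$HBMFORGE", bl)) {
            mr <- regmatches(bl, regexec("region=([^ ]+)", bl))[[1]]
            if (length(mr) == 2) region <- mr[2]
            md <- regmatches(bl, regexec("density=([^ ]+)", bl))[[1]]
            if (length(md) == 2) dens <- as.numeric(md[2])
          }
        } else if (nzchar(trimws(bl))) {
          if (is.na(title)) title <- trimws(bl)
          else if (is.na(dataline)) dataline <- j
        }
      }
      if (is.na(dataline))
        stop(sprintf("*PART card at line %d lacks a data line", i))
      v <- parse_numeric_fields(lines[[dataline]], rep(8, 3), dataline)
      parts[[length(parts) + 1L]] <-
        list(id = as.integer(v[1]), name = title, region = region,
             material = as.character(if (is.na(v[3])) NA else as.integer(v[3])),
             density = dens)
    } else if (kw == "*PARAMETER") {
      for (j in data_idx) {
        toks <- strsplit(gsub(",", " ", lines[[j]]), "[[:space:]]+")[[1]]
        toks <- toks[nzchar(toks)]
        if (length(toks) >= 3 && toupper(toks[1]) %in% c("R", "I")) {
          pname <- toks[2]; pval <- toks[3]
        } else if (length(toks) >= 2 && grepl("^[RIri]", toks[1]) &&
                   nchar(toks[1]) > 1) {
          pname <- substring(toks[1], 2); pval <- toks[2]
        } else {
          stop(sprintf("malformed parameter line %d", j))
        }
        val <- suppressWarnings(as.numeric(pval))
        if (is.na(val))
          stop(sprintf("malformed numeric field '%s' at line %d", pval, j))
        params[pname] <- val
      }
    } else if (kw == "*INCLUDE") {
      fn <- trimws(body[!is_comment(body) & nzchar(trimws(body))][1])
      if (is.na(fn) || !nzchar(fn))
        stop(sprintf("*INCLUDE at line %d names no file", i))
      inc_names <- c(inc_names, fn)
    } else if (kw %in% c("*KEYWORD", "*END")) {
      # structural markers, nothing to store
    } else {
      extra[[length(extra) + 1L]] <-
        list(keyword = kw, lines = c(line, body), include = name)
    }
    i <- block_end
  }

  to_df <- function(lst, cols) {
    if (!length(lst)) return(NULL)
    m <- do.call(rbind, lst)
    d <- as.data.frame(m)
    names(d) <- cols
    d
  }
  nd <- to_df(nodes, c("id", "x", "y", "z"))
  if (is.null(nd)) nd <- empty_nodes() else nd$id <- as.integer(nd$id)
  sd <- to_df(solids, c("id", "part", paste0("n", 1:8)))
  if (is.null(sd)) sd <- empty_solids() else sd[] <- lapply(sd, as.integer)
  sh <- to_df(shells, c("id", "part", paste0("n", 1:4), "thickness"))
  if (is.null(sh)) {
    sh <- empty_shells()
  } else {
    sh[1:6] <- lapply(sh[1:6], as.integer)
  }
  di <- to_df(discretes, c("id", "part", "n1", "n2"))
  if (is.null(di)) di <- empty_discretes() else di[] <- lapply(di, as.integer)
  pt <- if (length(parts)) {
    do.call(rbind, lapply(parts, function(p) as.data.frame(p)))
  } else {
    empty_parts()
  }
  nd$include <- if (nrow(nd)) name else character(0)
  if (nrow(sd)) sd$include <- name else sd$include <- character(0)
  if (nrow(sh)) sh$include <- name else sh$include <- character(0)
  if (nrow(di)) di$include <- name else di$include <- character(0)
  if (nrow(pt)) pt$include <- name else pt$include <- character(0)

  dup <- nd$id[duplicated(nd$id)]
  if (length(dup))
    stop("duplicate node id(s): ", paste(unique(dup), collapse = ", "))

  includes <- data.frame(name = inc_names,
                         role = rep("unresolved", length(inc_names)))
  hbm_assembly(nodes = nd, solids = sd, shells = sh, discretes = di,
               parts = pt, parameters = params, includes = includes,
               extra = extra, validate = FALSE)
}

include_role <- function(frag) {
  has_nodes <- nrow(frag$nodes) > 0
  has_other <- nrow(frag$solids) + nrow(frag$shells) + nrow(frag$discretes) > 0
  has_parts <- nrow(frag$parts) > 0
  if (has_nodes && !has_other && !has_parts) "nodes"
  else if (has_parts || has_other) "region-definition"
  else "control"
}

#' Resolve the include graph of a main keyword file
#'
#' Reads the main file, recursively resolves every `*INCLUDE` it references
#' (relative to the main file's directory by default, or through a custom
#' resolver), and merges all fragments into one assembly.  Entity counts of
#' the merged assembly equal the sums over fragments, and every entity keeps
#' the name of the include it came from as provenance.
#'
#' @param main path to the main keyword file.
#' @param resolver optional function `(include_name) -> path or character
#'   lines`; defaults to resolving paths relative to `dirname(main)`.
#' @return Merged `hbm_assembly`; include roles are classified from content
#'   (`nodes` for nodes-only files, `region-definition` for element/part
#'   files, `control` otherwise).
#' @export
resolve_includes <- function(main, resolver = NULL) {
  base_dir <- if (is.character(main) && length(main) == 1 &&
                  file.exists(main)) dirname(main) else "."
  if (is.null(resolver)) {
    resolver <- function(nm) {
      p <- file.path(base_dir, nm)
      if (!file.exists(p)) stop("missing include file: ", nm)
      p
    }
  }
  frags <- list(); roles <- character()
  visit <- function(input, name, stack) {
    if (name %in% stack)
      stop("cyclic include: ", paste(c(stack, name), collapse = " -> "))
    frag <- parse_keyword_file(input, name = name)
    frags[[name]] <<- frag
    roles[name] <<- include_role(frag)
    for (child in frag$includes$name) {
      src <- tryCatch(resolver(child),
                      error = function(e) stop("missing include file: ",
                                               child, call. = FALSE))
      visit(src, child, c(stack, name))
    }
  }
  visit(main, "main", character())

  bind <- function(field) {
    tabs <- lapply(frags, `[[`, field)
    do.call(rbind, tabs[vapply(tabs, nrow, 1L) > 0] )
  }
  nd <- bind("nodes"); if (is.null(nd)) nd <- empty_nodes()
  rownames(nd) <- NULL
  merged <- hbm_assembly(
    nodes = nd,
    solids = { t <- bind("solids"); if (is.null(t)) empty_solids() else t },
    shells = { t <- bind("shells"); if (is.null(t)) empty_shells() else t },
    discretes = { t <- bind("discretes"); if (is.null(t)) empty_discretes()
                  else t },
    parts = { t <- bind("parts"); if (is.null(t)) empty_parts() else t },
    parameters = unlist(unname(lapply(frags, `[[`, "parameters"))),
    includes = data.frame(name = names(roles), role = unname(roles)),
    extra = do.call(c, unname(lapply(frags, `[[`, "extra"))),
    validate = FALSE)
  for (f in c("solids", "shells", "discretes", "parts"))
    rownames(merged[[f]]) <- NULL
  validate_assembly(merged)
  merged
}

# canonical decimal representation: the shortest string (fewest characters,
# then fewest digits) that reparses to the same double and fits the field;
# falls back to the most precise fitting representation.  The rule is a
# fixed point: re-formatting the reparsed value reproduces the same string,
# so write -> parse -> write is stable.
format_coord <- function(x, width = 16L) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    v <- x[[k]]
    best <- NULL; fallback <- NULL
    for (dg in 1:17) {
      cand <- formatC(v, digits = dg, format = "g", width = 0)
      if (nchar(cand) > width) next
      fallback <- cand
      if (as.numeric(cand) == v &&
          (is.null(best) || nchar(cand) < nchar(best))) best <- cand
    }
    s <- if (!is.null(best)) best else fallback
    if (is.null(s))
      stop("coordinate ", v, " does not fit a ", width,
           "-character field; use the comma dialect")
    out[k] <- s
  }
  out
}

fmt_int8 <- function(v, what = "id") {
  if (any(v > 99999999 | v < -9999999))
    stop(what, " overflows the 8-character fixed-width field ",
         "(use the comma dialect)")
  sprintf("%8d", as.integer(v))
}

emit_block <- function(assembly, unit, dialect) {
  out <- character()
  nd <- assembly$nodes[is_unit(assembly$nodes$include, unit), , drop = FALSE]
  if (nrow(nd)) {
    out <- c(out, "*NODE")
    cs <- format_coord(c(nd$x, nd$y, nd$z))
    m <- matrix(cs, ncol = 3)
    if (dialect == "fixed") {
      out <- c(out, paste0(fmt_int8(nd$id, "node id"),
                           formatC(m[, 1], width = 16),
                           formatC(m[, 2], width = 16),
                           formatC(m[, 3], width = 16)))
    } else {
      out <- c(out, paste(nd$id, m[, 1], m[, 2], m[, 3], sep = ","))
    }
  }
  emit_elems <- function(tab, kw, cols) {
    if (!nrow(tab)) return(character())
    vals <- as.matrix(tab[, cols, drop = FALSE])
    if (dialect == "fixed") {
      rows <- apply(vals, 1, function(r)
        paste0(fmt_int8(r[!is.na(r)], "element field"), collapse = ""))
    } else {
      rows <- apply(vals, 1, function(r)
        paste(r[!is.na(r)], collapse = ","))
    }
    c(kw, rows)
  }
  so <- assembly$solids[is_unit(assembly$solids$include, unit), , drop = FALSE]
  out <- c(out, emit_elems(so, "*ELEMENT_SOLID", c("id", "part",
                                                   paste0("n", 1:8))))
  sh <- assembly$shells[is_unit(assembly$shells$include, unit), , drop = FALSE]
  if (nrow(sh)) {
    out <- c(out, "*ELEMENT_SHELL")
    for (r in seq_len(nrow(sh))) {
      ints <- unlist(sh[r, c("id", "part", paste0("n", 1:4))])
      row <- if (dialect == "fixed") {
        paste0(paste0(fmt_int8(ints, "element field"), collapse = ""),
               if (!is.na(sh$thickness[r]))
                 formatC(format_coord(sh$thickness[r], 8), width = 8) else "")
      } else {
        paste(c(ints, if (!is.na(sh$thickness[r]))
          format_coord(sh$thickness[r], 16)), collapse = ",")
      }
      out <- c(out, row)
    }
  }
  di <- assembly$discretes[is_unit(assembly$discretes$include, unit),
                           , drop = FALSE]
  out <- c(out, emit_elems(di, "*ELEMENT_DISCRETE",
                           c("id", "part", "n1", "n2")))
  pt <- assembly$parts[is_unit(assembly$parts$include, unit), , drop = FALSE]
  for (r in seq_len(nrow(pt))) {
    out <- c(out, "*PART", pt$name[r])
    meta <- character()
    if (!is.na(pt$region[r])) meta <- c(meta, paste0("region=", pt$region[r]))
    if (!is.na(pt$density[r]))
      meta <- c(meta, paste0("density=", format_coord(pt$density[r])))
    if (length(meta))
      out <- c(out, paste("$HBMFORGE", paste(meta, collapse = " ")))
    mid <- suppressWarnings(as.integer(pt$material[r]))
    ints <- c(pt$id[r], 0L, if (is.na(mid)) NULL else mid)
    out <- c(out, if (dialect == "fixed")
      paste0(fmt_int8(ints, "part field"), collapse = "")
      else paste(ints, collapse = ","))
  }
  for (blk in assembly$extra)
    if (is_unit(blk$include, unit)) out <- c(out, blk$lines)
  out
}

is_unit <- function(include, unit) {
  if (unit == "main") is.na(include) | include == "main"
  else !is.na(include) & include == unit
}

#' Write an assembly back to keyword text
#'
#' Emits one text stream per logical include unit, grouping entities by
#' their include provenance (entities without provenance go to the main
#' stream, which also carries the `*INCLUDE` references, `*PARAMETER` card
#' and `*KEYWORD`/`*END` markers).  Reading the written streams back
#' reproduces node coordinates bit-identically whenever their shortest
#' round-trip decimal representation fits the 16-character field (always
#' true in the comma dialect) and reproduces all topology exactly.
#'
#' @param assembly `hbm_assembly`.
#' @param dialect `"fixed"` (8-character integer / 16-character float
#'   fields, the default) or `"comma"`.
#' @return Named list of character vectors, one per include unit plus
#'   `"main"`.
#' @export
write_keyword_files <- function(assembly, dialect = c("fixed", "comma")) {
  dialect <- match.arg(dialect)
  validate_assembly(assembly)
  units <- setdiff(unique(stats::na.omit(c(
    assembly$nodes$include, assembly$solids$include,
    assembly$shells$include, assembly$discretes$include,
    assembly$parts$include,
    vapply(assembly$extra, `[[`, "", "include")))), "main")
  out <- list()
  main <- c("*KEYWORD")
  if (length(assembly$parameters)) {
    main <- c(main, "*PARAMETER",
              sprintf("R %s %s", names(assembly$parameters),
                      format_coord(unname(assembly$parameters))))
  }
  for (u in units) main <- c(main, "*INCLUDE", u)
  main <- c(main, emit_block(assembly, "main", dialect), "*END")
  out[["main"]] <- main
  for (u in units) out[[u]] <- emit_block(assembly, u, dialect)
  out
}

#' Write an assembly to a directory as a modular deck
#'
#' @param assembly `hbm_assembly`.
#' @param dir output directory (created if absent).
#' @param main_name file name for the main deck.
#' @param dialect passed to [write_keyword_files()].
#' @return Invisibly, the path to the written main file.
#' @export
write_deck <- function(assembly, dir, main_name = "main.k",
                       dialect = c("fixed", "comma")) {
  streams <- write_keyword_files(assembly, dialect = match.arg(dialect))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(streams)) {
    fn <- if (nm == "main") main_name else nm
    writeLines(streams[[nm]], file.path(dir, fn))
  }
  invisible(file.path(dir, main_name))
}

#' Assemble a model variant from shared includes plus a nodes include
#'
#' The lineup's derivative models share every include except the node
#' coordinates and the parameter settings.  This operation swaps the node
#' table of a model for a variant node set (same ids, new coordinates) and
#' overrides parameters, leaving element tables, parts and opaque cards
#' untouched.
#'
#' @param shared `hbm_assembly` providing everything except the variant
#'   nodes (its own node table is discarded).
#' @param nodes data.frame with `id`, `x`, `y`, `z` (an `hbm_assembly`
#'   fragment is also accepted, in which case its node table is used).
#' @param parameters named list/vector of parameter overrides.
#' @return `hbm_assembly` of the variant.  Errors listing the missing ids
#'   if an element references a node absent from the variant node set.
#' @export
assemble_variant <- function(shared, nodes, parameters = NULL) {
  if (inherits(nodes, "hbm_assembly")) nodes <- nodes$nodes
  nodes <- as.data.frame(nodes)
  need <- unique(c(
    unlist(shared$solids[paste0("n", 1:8)], use.names = FALSE),
    unlist(shared$shells[paste0("n", 1:4)], use.names = FALSE),
    unlist(shared$discretes[c("n1", "n2")], use.names = FALSE)))
  missing <- setdiff(need, nodes$id)
  if (length(missing))
    stop("variant node set is missing node id(s): ",
         paste(utils::head(sort(missing), 20), collapse = ", "))
  if (is.null(nodes$include)) nodes$include <- "nodes.k"
  params <- shared$parameters
  if (!is.null(parameters)) {
    pv <- unlist(parameters)
    params[names(pv)] <- pv
  }
  hbm_assembly(nodes = nodes, solids = shared$solids, shells = shared$shells,
               discretes = shared$discretes, parts = shared$parts,
               parameters = params, includes = shared$includes,
               extra = shared$extra)
}

#' Structural diff of two assemblies
#'
#' Two variants of the same lineup must be identical outside node
#' coordinates and parameter values.  This compares element tables, parts
#' and opaque card blocks, and summarizes what differs.
#'
#' @param a,b `hbm_assembly` objects.
#' @return List with logical `structure_identical` (element/part/opaque
#'   equality, node ids equal), `nodes_moved` (count of nodes whose
#'   coordinates differ), and `parameters_changed` (names).
#' @export
assembly_diff <- function(a, b) {
  strip <- function(tab) {
    tab <- tab[setdiff(names(tab), "include")]
    rownames(tab) <- NULL
    tab
  }
  same <- isTRUE(all.equal(strip(a$solids), strip(b$solids))) &&
    isTRUE(all.equal(strip(a$shells), strip(b$shells))) &&
    isTRUE(all.equal(strip(a$discretes), strip(b$discretes))) &&
    isTRUE(all.equal(strip(a$parts), strip(b$parts))) &&
    identical(lapply(a$extra, `[[`, "lines"),
              lapply(b$extra, `[[`, "lines")) &&
    identical(sort(a$nodes$id), sort(b$nodes$id))
  an <- a$nodes[order(a$nodes$id), c("x", "y", "z")]
  bn <- b$nodes[order(b$nodes$id), c("x", "y", "z")]
  moved <- if (nrow(an) == nrow(bn))
    sum(rowSums(abs(as.matrix(an) - as.matrix(bn))) > 0) else NA_integer_
  pn <- union(names(a$parameters), names(b$parameters))
  changed <- pn[vapply(pn, function(p)
    !isTRUE(all.equal(a$parameters[p], b$parameters[p])), TRUE)]
  list(structure_identical = same, nodes_moved = moved,
       parameters_changed = changed)
}

#' Node coordinates as a matrix
#'
#' @param assembly `hbm_assembly`.
#' @return Numeric matrix with one row per node, rownames the node ids.
#' @export
node_matrix <- function(assembly) {
  m <- as.matrix(assembly$nodes[c("x", "y", "z")])
  rownames(m) <- assembly$nodes$id
  m
}

#' Replace node coordinates
#'
#' @param assembly `hbm_assembly`.
#' @param coords matrix as returned by [node_matrix()] (same row order).
#' @return `hbm_assembly` with updated coordinates; ids untouched.
#' @export
set_node_matrix <- function(assembly, coords) {
  stopifnot(nrow(coords) == nrow(assembly$nodes))
  assembly$nodes$x <- coords[, 1]
  assembly$nodes$y <- coords[, 2]
  assembly$nodes$z <- coords[, 3]
  assembly
}
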