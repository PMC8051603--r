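# Chromosomes are ordered lists of oriented ancestral segments. A segment is
# a row (source, start, end, orient) with 1-based inclusive span in ancestral
# gene-rank units of the source proto-chromosome; traversal of a '-' segment
# runs end -> start. Satellites are telomere-derived fragments with no gene
# content; their loss reduces the chromosome number.

new_chromosome <- function(id, segments, is_satellite = FALSE) {
  list(id = id, segments = segments, is_satellite = is_satellite)
}

empty_segments <- function() {
  data.frame(source = character(0), start = integer(0), end = integer(0),
             orient = character(0), stringsAsFactors = FALSE)
}

#' Construct a karyotype
#'
#' @param node_label label of the evolutionary node (e.g. `"E"`, `"H"`,
#'   `"P"`, `"Q"`, `"R"`, or a species name).
#' @param chromosomes list of chromosomes (`new_ancestral_karyotype()` is the
#'   usual entry point).
#' @return list of class `karyotype`.
#' @export
karyotype <- function(node_label, chromosomes) {
  ids <- vapply(chromosomes, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate chromosome ids: ", ids[duplicated(ids)][1])
  structure(list(node_label = node_label,
                 chromosomes = stats::setNames(chromosomes, ids)),
            class = "karyotype")
}

#' Ancestral karyotype of single-source chromosomes
#'
#' @param labels chromosome labels (e.g. `paste0("E", 1:7)`).
#' @param sizes gene counts per chromosome (recycled).
#' @param node_label node label.
#' @return a [karyotype()] whose chromosome i is one `+` segment spanning
#'   gene ranks `1..sizes[i]` of source `labels[i]`.
#' @export
new_ancestral_karyotype <- function(labels, sizes = 100L, node_label = "E") {
  sizes <- rep_len(as.integer(sizes), length(labels))
  chroms <- Map(function(lab, sz) new_chromosome(lab, data.frame(
    source = lab, start = 1L, end = sz, orient = "+",
    stringsAsFactors = FALSE)), labels, sizes)
  karyotype(node_label, unname(chroms))
}

chrom_length <- function(chrom) {
  if (!nrow(chrom$segments)) return(0L)
  sum(chrom$segments$end - chrom$segments$start + 1L)
}

#' Non-satellite chromosome count
#' @param k a `karyotype`.
#' @return integer count.
#' @export
chromosome_count <- function(k) {
  sum(!vapply(k$chromosomes, `[[`, logical(1), "is_satellite"))
}

# split a segment table at cumulative position pos (keep first pos units);
# returns list(head=, tail=)
split_segments_at <- function(segments, pos) {
  total <- if (nrow(segments)) sum(segments$end - segments$start + 1L) else 0L
  if (pos < 0L || pos > total)
    stop("breakpoint ", pos, " out of range (chromosome has ", total, " units)")
  if (pos == 0L) return(list(head = empty_segments(), tail = segments))
  if (pos == total) return(list(head = segments, tail = empty_segments()))
  cum <- 0L
  for (i in seq_len(nrow(segments))) {
    len <- segments$end[i] - segments$start[i] + 1L
    if (cum + len >= pos) {
      take <- pos - cum
      head <- segments[seq_len(i - 1L), , drop = FALSE]
      tail <- segments[seq_len(nrow(segments)) > i, , drop = FALSE]
      seg <- segments[i, , drop = FALSE]
      if (take == len) {
        head <- rbind(head, seg)
      } else if (seg$orient == "+") {
        s1 <- seg; s1$end <- seg$start + take - 1L
        s2 <- seg; s2$start <- seg$start + take
        head <- rbind(head, s1); tail <- rbind(s2, tail)
      } else {
        s1 <- seg; s1$start <- seg$end - take + 1L
        s2 <- seg; s2$end <- seg$end - take
        head <- rbind(head, s1); tail <- rbind(s2, tail)
      }
      rownames(head) <- rownames(tail) <- NULL
      return(list(head = head, tail = tail))
    }
    cum <- cum + len
  }
  stop("unreachable")
}

# ordered (source, unit) traversal of a chromosome, orientation-aware;
# invariant under cosmetic segment splits
segment_traversal <- function(chrom) {
  if (!nrow(chrom$segments)) return(data.frame(source = character(0),
                                               unit = integer(0)))
  pieces <- lapply(seq_len(nrow(chrom$segments)), function(i) {
    s <- chrom$segments[i, ]
    units <- if (s$orient == "+") s$start:s$end else s$end:s$start
    data.frame(source = s$source, unit = units)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

flip_segments <- function(segments) {
  if (!nrow(segments)) return(segments)
  out <- segments[rev(seq_len(nrow(segments))), , drop = FALSE]
  out$orient <- ifelse(out$orient == "+", "-", "+")
  rownames(out) <- NULL
  out
}

#' Create a karyotype event
#'
#' @param kind one of `WGT, WGD, X, EJ, NCF, Inv, SatLoss, Rename`.
#' @param operands chromosome ids the event acts on.
#' @param breakpoints cumulative gene-rank positions (X: one per operand;
#'   NCF: one, in the host; Inv: `c(from, to)` range).
#' @param products ids of product chromosomes.
#' @param satellite id of the emitted satellite (EJ, NCF).
#' @return list of class `karyotype_event`.
#' @export
karyotype_event <- function(kind, operands = character(0),
                            breakpoints = integer(0),
                            products = character(0), satellite = NULL) {
  kind <- match.arg(kind, c("WGT", "WGD", "X", "EJ", "NCF", "Inv",
                            "SatLoss", "Rename"))
  structure(list(kind = kind, operands = operands,
                 breakpoints = as.integer(breakpoints),
                 products = products, satellite = satellite),
            class = "karyotype_event")
}

#' Apply one event to a karyotype
#'
#' * `WGD` / `WGT` replicate every non-satellite chromosome, suffixing copies
#'   `a`/`b`(/`c`).
#' * `X` (crossover) exchanges the distal arms of two chromosomes at their
#'   breakpoints.
#' * `EJ` joins two chromosomes end to end; `NCF` inserts the first operand
#'   into the second at the breakpoint. Both emit a telomere-derived,
#'   gene-free satellite.
#' * `Inv` reverses the segment range between two cumulative positions,
#'   flipping orientations.
#' * `SatLoss` removes a satellite; `Rename` relabels a chromosome.
#'
#' Segment content is conserved by every event except `SatLoss` (satellites
#' are gene-free, so gene content is conserved there too).
#'
#' @param k a `karyotype`.
#' @param e a [karyotype_event()].
#' @return the resulting `karyotype`.
#' @export
apply_event <- function(k, e) {
  stopifnot(inherits(k, "karyotype"), inherits(e, "karyotype_event"))
  get_chrom <- function(id) {
    if (!id %in% names(k$chromosomes)) stop("unknown chromosome: ", id)
    k$chromosomes[[id]]
  }
  chroms <- k$chromosomes
  if (e$kind %in% c("WGD", "WGT")) {
    suff <- if (e$kind == "WGD") c("a", "b") else c("a", "b", "c")
    out <- list()
    for (ch in chroms) {
      if (ch$is_satellite) { out[[length(out) + 1L]] <- ch; next }
      for (s in suff) {
        cp <- ch; cp$id <- paste0(ch$id, s)
        out[[length(out) + 1L]] <- cp
      }
    }
    return(karyotype(k$node_label, out))
  }
  if (e$kind == "X") {
    c1 <- get_chrom(e$operands[1]); c2 <- get_chrom(e$operands[2])
    s1 <- split_segments_at(c1$segments, e$breakpoints[1])
    s2 <- split_segments_at(c2$segments, e$breakpoints[2])
    p1 <- if (length(e$products) >= 1) e$products[1] else paste0(c1$id, "'")
    p2 <- if (length(e$products) >= 2) e$products[2] else paste0(c2$id, "'")
    chroms[[c1$id]] <- NULL; chroms[[c2$id]] <- NULL
    chroms[[p1]] <- new_chromosome(p1, rbind(s1$head, s2$tail))
    chroms[[p2]] <- new_chromosome(p2, rbind(s2$head, s1$tail))
    return(karyotype(k$node_label, unname(chroms)))
  }
  if (e$kind == "EJ") {
    c1 <- get_chrom(e$operands[1]); c2 <- get_chrom(e$operands[2])
    p <- if (length(e$products)) e$products[1] else paste0(c1$id, c2$id)
    chroms[[c1$id]] <- NULL; chroms[[c2$id]] <- NULL
    chroms[[p]] <- new_chromosome(p, rbind(c1$segments, c2$segments))
    if (!is.null(e$satellite))
      chroms[[e$satellite]] <- new_chromosome(e$satellite, empty_segments(),
                                              is_satellite = TRUE)
    return(karyotype(k$node_label, unname(chroms)))
  }
  if (e$kind == "NCF") {
    ins <- get_chrom(e$operands[1]); host <- get_chrom(e$operands[2])
    sh <- split_segments_at(host$segments, e$breakpoints[1])
    p <- if (length(e$products)) e$products[1] else paste0(host$id, ins$id)
    chroms[[ins$id]] <- NULL; chroms[[host$id]] <- NULL
    chroms[[p]] <- new_chromosome(p, rbind(sh$head, ins$segments, sh$tail))
    if (!is.null(e$satellite))
      chroms[[e$satellite]] <- new_chromosome(e$satellite, empty_segments(),
                                              is_satellite = TRUE)
    return(karyotype(k$node_label, unname(chroms)))
  }
  if (e$kind == "Inv") {
    ch <- get_chrom(e$operands[1])
    from <- e$breakpoints[1]; to <- e$breakpoints[2]
    if (from < 1L || to < from) stop("invalid inversion range")
    s1 <- split_segments_at(ch$segments, from - 1L)
    s2 <- split_segments_at(s1$tail, to - from + 1L)
    ch$segments <- rbind(s1$head, flip_segments(s2$head), s2$tail)
    rownames(ch$segments) <- NULL
    chroms[[ch$id]] <- ch
    return(karyotype(k$node_label, unname(chroms)))
  }
  if (e$kind == "SatLoss") {
    ch <- get_chrom(e$operands[1])
    if (!ch$is_satellite) stop("SatLoss on non-satellite chromosome: ", ch$id)
    chroms[[ch$id]] <- NULL
    return(karyotype(k$node_label, unname(chroms)))
  }
  if (e$kind == "Rename") {
    ch <- get_chrom(e$operands[1])
    chroms[[ch$id]] <- NULL
    ch$id <- e$products[1]
    chroms[[ch$id]] <- ch
    return(karyotype(k$node_label, unname(chroms)))
  }
  stop("unhandled event kind: ", e$kind)
}

#' Parse an event script
#'
#' One event per line:
#' \preformatted{
#' NODE P                    # checkpoint
#' WGD                       # or WGT
#' X  c1@12 c2@30 -> n1 n2   # arm exchange at cumulative positions
#' EJ c3 c4 -> c5 +S1        # end-to-end joining, satellite S1
#' NCF c6 c7@15 -> c8 +S2    # c6 inserted into c7 at 15
#' INV c5 4..9               # segmental inversion
#' LOSS S1                   # satellite loss
#' REN old new               # rename
#' }
#' `#` starts a comment; blank lines are ignored.
#'
#' @param x path to a script file, or a character vector of lines.
#' @return list of class `event_script`: each element either
#'   `list(node = label)` or a [karyotype_event()], each carrying `line`.
#' @export
parse_event_script <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  items <- list()
  at <- function(op) {
    m <- regmatches(op, regexec("^([^@]+)@(\\d+)$", op))[[1]]
    if (length(m)) list(id = m[2], pos = as.integer(m[3]))
    else list(id = op, pos = NA_integer_)
  }
  for (ln_no in seq_along(lines)) {
    ln <- sub("#.*", "", lines[ln_no])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    kw <- toupper(f[1])
    item <- tryCatch(switch(
      kw,
      NODE = list(node = f[2]),
      WGD = karyotype_event("WGD"),
      WGT = karyotype_event("WGT"),
      X = {
        arrow <- which(f == "->")
        a <- at(f[2]); b <- at(f[3])
        karyotype_event("X", operands = c(a$id, b$id),
                        breakpoints = c(a$pos, b$pos),
                        products = if (length(arrow)) f[(arrow + 1):(arrow + 2)]
                        else character(0))
      },
      EJ = {
        arrow <- which(f == "->")
        sat <- grep("^\\+", f, value = TRUE)
        prods <- if (length(arrow)) setdiff(f[(arrow + 1):length(f)], sat)
                 else character(0)
        karyotype_event("EJ", operands = f[2:3], products = prods,
                        satellite = if (length(sat)) sub("^\\+", "", sat[1]))
      },
      NCF = {
        arrow <- which(f == "->")
        sat <- grep("^\\+", f, value = TRUE)
        prods <- if (length(arrow)) setdiff(f[(arrow + 1):length(f)], sat)
                 else character(0)
        host <- at(f[3])
        karyotype_event("NCF", operands = c(f[2], host$id),
                        breakpoints = host$pos, products = prods,
                        satellite = if (length(sat)) sub("^\\+", "", sat[1]))
      },
      INV = {
        rng <- as.integer(strsplit(f[3], "..", fixed = TRUE)[[1]])
        karyotype_event("Inv", operands = f[2], breakpoints = rng)
      },
      LOSS = karyotype_event("SatLoss", operands = f[2]),
      REN = karyotype_event("Rename", operands = f[2], products = f[3]),
      stop("unknown event keyword: ", f[1])
    ), error = function(e)
      stop("event script line ", ln_no, ": ", conditionMessage(e)))
    item$line <- ln_no
    items[[length(items) + 1L]] <- item
  }
  structure(items, class = "event_script")
}

#' Serialise an event script back to its text form
#' @param script an `event_script`.
#' @return character vector of lines.
#' @export
format_event_script <- function(script) {
  vapply(script, function(it) {
    if (!is.null(it$node)) return(paste("NODE", it$node))
    switch(it$kind,
           WGD = "WGD", WGT = "WGT",
           X = paste0("X ", it$operands[1], "@", it$breakpoints[1], " ",
                      it$operands[2], "@", it$breakpoints[2], " -> ",
                      paste(it$products, collapse = " ")),
           EJ = paste0("EJ ", paste(it$operands, collapse = " "), " -> ",
                       paste(it$products, collapse = " "),
                       if (!is.null(it$satellite)) paste0(" +", it$satellite) else ""),
           NCF = paste0("NCF ", it$operands[1], " ", it$operands[2], "@",
                        it$breakpoints[1], " -> ",
                        paste(it$products, collapse = " "),
                        if (!is.null(it$satellite)) paste0(" +", it$satellite) else ""),
           Inv = paste0("INV ", it$operands[1], " ", it$breakpoints[1], "..",
                        it$breakpoints[2]),
           SatLoss = paste("LOSS", it$operands[1]),
           Rename = paste("REN", it$operands[1], it$products[1]))
  }, character(1))
}

#' Replay an event script, snapshotting every checkpoint
#'
#' @param initial initial `karyotype`; its `node_label` should match the
#'   script's first checkpoint if the script starts with one.
#' @param script an `event_script` (or path / lines, parsed on the fly).
#' @return list of class `karyotype_replay`: `snapshots` (named list of
#'   karyotypes, one per `NODE`), `final` karyotype, and `summary`
#'   data.frame (`node`, `n_chromosomes`, `n_satellites`).
#' @export
replay_script <- function(initial, script) {
  if (!inherits(script, "event_script")) script <- parse_event_script(script)
  k <- initial
  snapshots <- list()
  for (it in script) {
    if (!is.null(it$node)) {
      k$node_label <- it$node
      snapshots[[it$node]] <- k
    } else {
      k <- tryCatch(apply_event(k, it), error = function(e)
        stop("replay failed at script line ", it$line, ": ",
             conditionMessage(e)))
    }
  }
  if (!length(snapshots)) snapshots[[initial$node_label]] <- k
  summary <- data.frame(
    node = names(snapshots),
    n_chromosomes = vapply(snapshots, chromosome_count, integer(1)),
    n_satellites = vapply(snapshots, function(s)
      sum(vapply(s$chromosomes, `[[`, logical(1), "is_satellite")), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(snapshots = snapshots, final = k, summary = summary),
            class = "karyotype_replay")
}

#' Per-source covered gene-rank units of a karyotype
#'
#' Used for conservation checks: every event except satellite loss preserves
#' this content exactly (and satellites carry none).
#'
#' @param k a `karyotype`.
#' @return named list: source -> sorted integer vector of covered units
#'   (positions occur once per copy).
#' @export
segment_content <- function(k) {
  pieces <- do.call(rbind, lapply(k$chromosomes, function(ch) ch$segments))
  if (is.null(pieces) || !nrow(pieces)) return(list())
  out <- lapply(split(pieces, pieces$source), function(p)
    sort(unlist(Map(seq.int, p$start, p$end), use.names = FALSE)))
  out
}

#' Karyotype TSV dump (chromosome, segment order, source, span, orientation)
#' @param k a `karyotype`.
#' @param path output path.
#' @export
write_karyotype <- function(k, path) {
  rows <- do.call(rbind, lapply(k$chromosomes, function(ch) {
    if (!nrow(ch$segments))
      return(data.frame(chromosome = ch$id, segment = NA_integer_,
                        source = NA_character_, start = NA_integer_,
                        end = NA_integer_, orient = NA_character_,
                        satellite = ch$is_satellite))
    data.frame(chromosome = ch$id, segment = seq_len(nrow(ch$segments)),
               source = ch$segments$source, start = ch$segments$start,
               end = ch$segments$end, orient = ch$segments$orient,
               satellite = ch$is_satellite)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Path to the packaged Apiales chromosome-trajectory script
#'
#' A transcription of the eudicot-to-Apiaceae karyotype trajectory
#' (triplication of 7 proto-chromosomes to 21, reduction to 8 before the
#' Apiales WGD, to 10 before the Apiaceae WGD, and to the 11 Apiaceae
#' proto-chromosomes). Breakpoint-level detail beyond the published node
#' counts and named fusions is illustrative; the file header says so.
#'
#' @return file path.
#' @export
apiaceae_trajectory_script <- function() {
  system.file("extdata", "apiaceae_trajectory.events", package = "wgdkit",
              mustWork = TRUE)
}

#' The pre-triplication eudicot ancestor karyotype (E1-E7)
#' @param genes_per_chromosome gene-rank units per proto-chromosome.
#' @return a `karyotype` with chromosomes E1..E7.
#' @export
eudicot_ancestor <- function(genes_per_chromosome = 100L) {
  new_ancestral_karyotype(paste0("E", 1:7), genes_per_chromosome, "E")
}
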