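#' Tile a genome into fixed-size contigs with ground truth
#'
#' Cuts a genome into consecutive chunks, the contig set a synthetic
#' assembly experiment scaffolds back together. The returned truth table
#' feeds [count_misjoins()].
#'
#' @param genome A `sim_genome` (or any list with `id`, `seq`, `length`).
#' @param contig_len Chunk length in bp; the last chunk keeps the
#'   remainder.
#' @return List with `contigs` (tibble `contig`, `start`, `length`,
#'   `seq`) and `truth` (tibble `contig`, `truth_seq`, `start`, `strand`,
#'   `length`).
#' @export
tile_contigs <- function(genome, contig_len) {
  starts <- seq.int(0L, genome$length - 1L, by = as.integer(contig_len))
  lens <- pmin(contig_len, genome$length - starts)
  contigs <- tibble::tibble(
    contig = sprintf("ctg%04d", seq_along(starts)),
    start = starts,
    length = as.integer(lens),
    seq = toupper(stringr::str_sub(genome$seq, starts + 1L, starts + lens))
  )
  truth <- tibble::tibble(
    contig = contigs$contig, truth_seq = genome$id, start = contigs$start,
    strand = "+", length = contigs$length
  )
  list(contigs = contigs, truth = truth)
}

#' Derive contig-joining links from mate-pair placements
#'
#' Converts mapped mate-pair reads into scaffolding links between contig
#' ends, the information an assembler's scaffolding phase uses. Each read
#' is assigned to the contig containing it entirely; a pair whose mates
#' land on two different contigs asserts a junction between the contig
#' end its `+`-strand read points out of and the end its `-`-strand read
#' points out of, with implied gap `Ln` minus the two overhangs.
#'
#' @param aln SAM tibble of the mate-pair reads placed on the genome the
#'   contigs tile (e.g. from [truth_align()]); qnames `<pair>/1|2`.
#' @param contigs Contig tibble from [tile_contigs()].
#' @param expected_insert Library insert size `Ln` in bp, or a
#'   per-pair lookup tibble (`pair_id`, `insert_size`).
#' @return Tibble of cross-contig links: `pair_id`, `contig_a`, `end_a`
#'   (`L`/`R`), `contig_b`, `end_b`, `gap`.
#' @export
pair_links <- function(aln, contigs, expected_insert) {
  a <- dplyr::filter(aln, .data$mapped, !.data$is_secondary_or_supplementary)
  if (nrow(a) == 0) {
    return(tibble::tibble(pair_id = character(), contig_a = character(),
                          end_a = character(), contig_b = character(),
                          end_b = character(), gap = numeric()))
  }
  rl <- nchar(a$seq)
  idx <- findInterval(a$pos, contigs$start)
  cstart <- contigs$start[idx]
  clen <- contigs$length[idx]
  inside <- a$pos >= cstart & (a$pos + rl) <= (cstart + clen)
  a <- a[inside, ]; idx <- idx[inside]; rl <- rl[inside]
  local <- a$pos - contigs$start[idx]
  ends <- ifelse(a$strand == "+", "R", "L")
  overhang <- ifelse(a$strand == "+", contigs$length[idx] - local, local + rl)
  placed <- tibble::tibble(
    pair_id = sub("/[12]$", "", a$qname),
    mate = ifelse(grepl("/2$", a$qname), 2L, 1L),
    contig = contigs$contig[idx],
    end = ends, overhang = overhang
  )
  wide <- dplyr::inner_join(
    dplyr::filter(placed, .data$mate == 1L),
    dplyr::filter(placed, .data$mate == 2L),
    by = "pair_id", suffix = c("_1", "_2")
  ) |>
    dplyr::filter(.data$contig_1 != .data$contig_2)
  ln <- if (is.numeric(expected_insert)) {
    tibble::tibble(pair_id = wide$pair_id, insert_size = expected_insert)
  } else {
    expected_insert
  }
  swap <- wide$contig_1 > wide$contig_2
  links <- tibble::tibble(
    pair_id = wide$pair_id,
    contig_a = ifelse(swap, wide$contig_2, wide$contig_1),
    end_a = ifelse(swap, wide$end_2, wide$end_1),
    contig_b = ifelse(swap, wide$contig_1, wide$contig_2),
    end_b = ifelse(swap, wide$end_1, wide$end_2),
    total_overhang = wide$overhang_1 + wide$overhang_2
  ) |>
    dplyr::left_join(ln, by = "pair_id") |>
    dplyr::mutate(gap = .data$insert_size - .data$total_overhang) |>
    dplyr::select("pair_id", "contig_a", "end_a", "contig_b", "end_b", "gap")
  links
}

#' Greedy scaffolding from contig-end links
#'
#' A deliberately minimal scaffolder used only to evaluate filtering
#' strategies: links are bundled by (contig end, contig end) signature,
#' bundles are taken in decreasing support order, and a bundle is
#' accepted when both ends are still free and joining does not close a
#' cycle. Not a production assembler.
#'
#' @param links Link tibble from [pair_links()].
#' @param contigs Contig tibble from [tile_contigs()].
#' @param min_support Minimum number of supporting pairs per bundle
#'   (default 2).
#' @return AGP-like joins tibble for [count_misjoins()]: `scaffold`,
#'   `idx`, `contig`, `orientation`, `gap` (median implied gap to the
#'   next contig; `NA` on each scaffold's last row).
#' @export
greedy_scaffold <- function(links, contigs, min_support = 2L) {
  bundles <- links |>
    dplyr::group_by(.data$contig_a, .data$end_a, .data$contig_b, .data$end_b) |>
    dplyr::summarise(support = dplyr::n(),
                     gap = stats::median(.data$gap), .groups = "drop") |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::arrange(dplyr::desc(.data$support), .data$contig_a, .data$end_a,
                   .data$contig_b, .data$end_b)

  ids <- contigs$contig
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  end_key <- function(ctg, end) paste0(ctg, ":", end)
  used <- character()
  edges <- list()
  for (k in seq_len(nrow(bundles))) {
    b <- bundles[k, ]
    ka <- end_key(b$contig_a, b$end_a)
    kb <- end_key(b$contig_b, b$end_b)
    if (ka %in% used || kb %in% used) next
    ia <- match(b$contig_a, ids); ib <- match(b$contig_b, ids)
    ra <- find(ia); rb <- find(ib)
    if (ra == rb) next
    parent[ra] <- rb
    used <- c(used, ka, kb)
    edges[[length(edges) + 1L]] <- b
  }
  edges <- dplyr::bind_rows(edges)

  # adjacency: contig end -> (neighbour contig, neighbour end, gap)
  adj <- new.env(parent = emptyenv())
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      b <- edges[k, ]
      assign(end_key(b$contig_a, b$end_a),
             list(ctg = b$contig_b, end = b$end_b, gap = b$gap), envir = adj)
      assign(end_key(b$contig_b, b$end_b),
             list(ctg = b$contig_a, end = b$end_a, gap = b$gap), envir = adj)
    }
  }
  linked_end <- function(ctg, end) {
    key <- end_key(ctg, end)
    if (exists(key, envir = adj)) get(key, envir = adj) else NULL
  }

  visited <- character()
  rows <- list()
  scaf_i <- 0L
  for (ctg in ids) {
    if (ctg %in% visited) next
    # start from a free end so the walk covers the whole chain
    start_end <- if (is.null(linked_end(ctg, "L"))) "L" else "R"
    if (!is.null(linked_end(ctg, start_end))) {
      # both ends linked mid-chain; its chain will be reached from a tip
      tip_free <- is.null(linked_end(ctg, "L")) || is.null(linked_end(ctg, "R"))
      if (!tip_free) next
    }
    scaf_i <- scaf_i + 1L
    cur <- ctg; enter <- start_end; i <- 0L
    repeat {
      i <- i + 1L
      orientation <- if (enter == "L") "+" else "-"
      exit <- if (enter == "L") "R" else "L"
      nxt <- linked_end(cur, exit)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scaffold = sprintf("scaffold%03d", scaf_i), idx = i, contig = cur,
        orientation = orientation,
        gap = if (is.null(nxt)) NA_real_ else nxt$gap
      )
      visited <- c(visited, cur)
      if (is.null(nxt)) break
      cur <- nxt$ctg
      enter <- nxt$end
    }
  }
  # contigs left unvisited can only sit on cycles, which the union-find
  # forbids, or be mid-chain (reached above); emit any stragglers singly
  left <- setdiff(ids, visited)
  for (ctg in left) {
    scaf_i <- scaf_i + 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      scaffold = sprintf("scaffold%03d", scaf_i), idx = 1L, contig = ctg,
      orientation = "+", gap = NA_real_
    )
  }
  dplyr::bind_rows(rows)
}

#' Scaffold lengths implied by a joins table
#'
#' Sums contig lengths and non-negative declared gaps per scaffold, for
#' contiguity statistics such as [n50()].
#'
#' @param joins Joins tibble (as from [greedy_scaffold()]).
#' @param contigs Contig tibble with `contig` and `length`.
#' @return Named numeric vector of scaffold lengths.
#' @export
scaffold_lengths <- function(joins, contigs) {
  j <- dplyr::left_join(joins, dplyr::select(contigs, "contig", "length"),
                        by = "contig")
  out <- j |>
    dplyr::group_by(.data$scaffold) |>
    dplyr::summarise(
      len = sum(.data$length) + sum(pmax(.data$gap[-dplyr::n()], 0),
                                    na.rm = TRUE),
      .groups = "drop"
    )
  stats::setNames(out$len, out$scaffold)
}
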