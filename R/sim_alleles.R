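#' Generate alleles with construction-forced consequence categories
#'
#' Places substitutions, small indels and whole-transcript deletions on a
#' [sim_genome()] output so that each allele's consequence category is forced
#' by construction: a missense allele is a non-synonymous, non-stop
#' substitution in coding sequence shared by every isoform; a synonymous
#' allele is a wobble substitution that preserves the amino acid and does
#' not create a GT dinucleotide (so it cannot be flagged as an ectopic
#' splice donor); splice alleles hit the canonical GT/AG dinucleotides; and
#' so on. Realized category counts follow the requested proportions by
#' largest-remainder apportionment (exact up to rounding). Deterministic per
#' seed.
#'
#' @param toy a `toy_genome`.
#' @param n number of alleles.
#' @param proportions named fractions over [supported_categories()],
#'   summing to 1.
#' @param seed integer seed (defaults to the config seed).
#' @return list with `alleles` (tibble: `chrom`, `pos` 0-based, `id`, `ref`,
#'   `alt`, `source`) and `truth` (tibble: `id`, `category`, `gene_id`).
#' @export
sim_alleles <- function(toy, n = toy$config$n_alleles,
                        proportions = toy$config$category_proportions,
                        seed = toy$config$seed) {
  stopifnot(inherits(toy, "toy_genome"))
  if (abs(sum(proportions) - 1) > 1e-9 || any(proportions < 0)) {
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  }
  bad <- setdiff(names(proportions), supported_categories())
  if (length(bad)) {
    stop("unsupported consequence category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (n == 0L) {
    return(list(
      alleles = tibble(chrom = character(0), pos = integer(0),
                       id = character(0), ref = character(0),
                       alt = character(0), source = character(0)),
      truth = tibble(id = character(0), category = character(0),
                     gene_id = character(0))
    ))
  }
  withr::with_seed(seed, build_alleles(toy, n, proportions))
}

# largest-remainder apportionment of n over named proportions
apportion <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    give <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[give] <- counts[give] + 1L
  }
  as.integer(counts)
}

build_alleles <- function(toy, n, proportions) {
  cfg <- toy$config
  plans <- toy$plan$genes
  gaps <- toy$plan$gaps
  chrom_seq <- setNames(as.character(toy$genome), names(toy$genome))
  flank <- cfg$flank_bp

  counts <- apportion(n, proportions)
  names(counts) <- names(proportions)
  cats <- rep(names(counts), counts)

  eligible <- function(cat) {
    ok <- vapply(plans, function(p) {
      switch(cat,
        splice_donor = ,
        splice_acceptor = p$n_int > 0L,
        intronic = p$n_int > 0L && any(p$introns$end - p$introns$start >= 12L),
        five_prime_UTR = p$u5 - 3L * p$ext_k >= 8L,
        three_prime_UTR = (p$u3 - (if (identical(p$pair_role, "A")) p$overlap_d else 0L)) >= 8L,
        transcript_ablation = is.na(p$pair_role),
        downstream = p$can_down,
        missense = ,
        synonymous = ,
        stop_gained = p$n_codons >= 5L,
        frameshift = any(p$chunks$end - p$chunks$start >= 16L),
        inframe_deletion = ,
        inframe_insertion = TRUE,
        TRUE)
    }, logical(1))
    which(ok)
  }

  rows <- vector("list", n)
  i_allele <- 0L
  for (cat in cats) {
    i_allele <- i_allele + 1L
    if (cat == "intergenic") {
      g <- gaps[sample.int(nrow(gaps), 1L), ]
      center <- (g$start + g$end) %/% 2L
      pos <- center + sample(-50:50, 1L)
      ref <- base_at(chrom_seq[[g$chrom]], pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      rows[[i_allele]] <- tibble(chrom = g$chrom, pos = pos, ref = ref,
                                 alt = alt, category = cat,
                                 gene_id = NA_character_)
      next
    }
    gi <- eligible(cat)
    if (!length(gi)) {
      stop("cannot generate '", cat,
           "' alleles: no eligible gene in the generated annotation",
           call. = FALSE)
    }
    made <- NULL
    for (try_gene in sample(rep(gi, 2L))) {
      made <- place_allele(cat, plans[[try_gene]], chrom_seq, flank)
      if (!is.null(made)) break
    }
    if (is.null(made)) {
      stop("failed to place a '", cat, "' allele", call. = FALSE)
    }
    rows[[i_allele]] <- made
  }
  out <- dplyr::bind_rows(rows)
  out$id <- sprintf("a%05d", seq_len(nrow(out)))
  is_sub <- nchar(out$ref) == 1L & nchar(out$alt) == 1L
  out$source <- ifelse(is_sub,
                       sample(c("forward_genetics", "crispr"), nrow(out),
                              replace = TRUE, prob = c(0.82, 0.18)),
                       "crispr")
  alleles <- out %>%
    select("chrom", "pos", "id", "ref", "alt", "source") %>%
    mutate(pos = as.integer(.data$pos))
  truth <- out %>% select("id", "category", "gene_id")
  list(alleles = alleles, truth = truth)
}

# place one allele of the requested category on one gene; NULL if this gene
# cannot host it (caller retries with another gene)
place_allele <- function(cat, p, chrom_seq, flank) {
  bases <- c("A", "C", "G", "T")
  cds_local <- unlist(purrr::map2(p$chunks$start, p$chunks$end,
                                  function(s, e) seq.int(s, e - 1L)))
  l2g <- function(l) if (p$strand == "+") p$offset + l else p$offset + p$len - 1L - l
  coding_base <- function(l) substr(p$gseq, l + 1L, l + 1L)
  sub_allele <- function(l, alt_coding) {
    pos <- l2g(l)
    if (p$strand == "+") {
      tibble(chrom = p$chrom, pos = pos, ref = coding_base(l),
             alt = alt_coding, category = cat, gene_id = p$gene_id)
    } else {
      tibble(chrom = p$chrom, pos = pos, ref = comp_chr(coding_base(l)),
             alt = comp_chr(alt_coding), category = cat, gene_id = p$gene_id)
    }
  }
  # deletion of local [ls, ls+dl), refusing positions that would left-align away
  del_allele <- function(ls, dl) {
    g0 <- if (p$strand == "+") p$offset + ls else p$offset + p$len - ls - dl
    ref <- seq_at(chrom_seq[[p$chrom]], g0, g0 + dl)
    if (g0 > 0L && base_at(chrom_seq[[p$chrom]], g0 - 1L) ==
        substr(ref, dl, dl)) {
      return(NULL)
    }
    tibble(chrom = p$chrom, pos = g0, ref = ref, alt = "",
           category = cat, gene_id = p$gene_id)
  }
  codon_at <- function(j) {
    ls <- cds_local[(3L * j + 1L):(3L * j + 3L)]
    paste0(coding_base(ls[1]), coding_base(ls[2]), coding_base(ls[3]))
  }
  n_cod <- length(cds_local) %/% 3L

  tries <- 0L
  repeat {
    tries <- tries + 1L
    if (tries > 200L) return(NULL)
    res <- switch(cat,
      missense = {
        j <- sample(seq.int(1L, n_cod - 2L), 1L)
        off <- sample(0:2, 1L)
        l <- cds_local[3L * j + off + 1L]
        cod <- codon_at(j)
        alt <- sample(setdiff(bases, substr(cod, off + 1L, off + 1L)), 1L)
        altcod <- cod; substr(altcod, off + 1L, off + 1L) <- alt
        aa0 <- translate_codons(cod); aa1 <- translate_codons(altcod)
        if (aa1 != aa0 && aa1 != "*") sub_allele(l, alt) else NULL
      },
      synonymous = {
        j <- sample(seq.int(1L, n_cod - 2L), 1L)
        off <- sample(0:2, 1L)
        l <- cds_local[3L * j + off + 1L]
        cod <- codon_at(j)
        alt <- sample(setdiff(bases, substr(cod, off + 1L, off + 1L)), 1L)
        altcod <- cod; substr(altcod, off + 1L, off + 1L) <- alt
        if (translate_codons(altcod) != translate_codons(cod)) {
          NULL
        } else {
          # refuse wobbles that create a GT in the +/-1 window: those would
          # be flagged as candidate ectopic splice donors downstream
          w_ref <- substr(p$gseq, l, l + 2L)
          w_alt <- w_ref; substr(w_alt, 2L, 2L) <- alt
          gt_at <- function(w) c(substr(w, 1, 2) == "GT", substr(w, 2, 3) == "GT")
          if (any(gt_at(w_alt) & !gt_at(w_ref))) NULL else sub_allele(l, alt)
        }
      },
      stop_gained = {
        j <- sample(seq.int(1L, n_cod - 2L), 1L)
        off <- sample(0:2, 1L)
        l <- cds_local[3L * j + off + 1L]
        cod <- codon_at(j)
        alt <- sample(setdiff(bases, substr(cod, off + 1L, off + 1L)), 1L)
        altcod <- cod; substr(altcod, off + 1L, off + 1L) <- alt
        if (translate_codons(altcod) == "*") sub_allele(l, alt) else NULL
      },
      stop_lost = {
        off <- sample(0:2, 1L)
        l <- cds_local[3L * (n_cod - 1L) + off + 1L]
        cod <- codon_at(n_cod - 1L)
        alt <- sample(setdiff(bases, substr(cod, off + 1L, off + 1L)), 1L)
        altcod <- cod; substr(altcod, off + 1L, off + 1L) <- alt
        if (translate_codons(altcod) != "*") sub_allele(l, alt) else NULL
      },
      start_lost = {
        off <- sample(0:2, 1L)
        l <- cds_local[off + 1L]
        cod <- codon_at(0L)
        alt <- sample(setdiff(bases, substr(cod, off + 1L, off + 1L)), 1L)
        sub_allele(l, alt)
      },
      frameshift = {
        big <- which(p$chunks$end - p$chunks$start >= 16L)
        if (!length(big)) return(NULL)
        ch <- p$chunks[sample(rep(big, 2L), 1L), ]
        dl <- sample(1:2, 1L)
        ls <- sample(seq.int(ch$start + 6L, ch$end - 6L - dl), 1L)
        del_allele(ls, dl)
      },
      inframe_deletion = {
        j <- sample(seq.int(1L, n_cod - 2L), 1L)
        ls3 <- cds_local[(3L * j + 1L):(3L * j + 3L)]
        if (ls3[3] != ls3[1] + 2L) NULL else del_allele(ls3[1], 3L)
      },
      inframe_insertion = {
        j <- sample(seq.int(1L, n_cod - 2L), 1L)
        l1 <- cds_local[3L * j + 1L]
        if (!((l1 - 1L) %in% cds_local)) return(NULL)
        cod <- sample(nonstop_codons(), 1L)
        # refuse codons whose edge bases would left-align the insertion
        if (substr(cod, 3L, 3L) == coding_base(l1 - 1L) ||
            substr(cod, 1L, 1L) == coding_base(l1)) {
          NULL
        } else {
          pos <- if (p$strand == "+") p$offset + l1 else p$offset + p$len - l1
          alt <- if (p$strand == "+") cod else revcomp_chr(cod)
          tibble(chrom = p$chrom, pos = pos, ref = "", alt = alt,
                 category = cat, gene_id = p$gene_id)
        }
      },
      transcript_ablation = {
        g0 <- p$offset - 5L
        ref <- seq_at(chrom_seq[[p$chrom]], g0, p$offset + p$len + 5L)
        tibble(chrom = p$chrom, pos = g0, ref = ref, alt = "",
               category = cat, gene_id = p$gene_id)
      },
      splice_donor = {
        it <- p$introns[sample.int(nrow(p$introns), 1L), ]
        l <- it$start + sample(0:1, 1L)
        alt <- sample(setdiff(bases, coding_base(l)), 1L)
        sub_allele(l, alt)
      },
      splice_acceptor = {
        it <- p$introns[sample.int(nrow(p$introns), 1L), ]
        l <- it$end - 2L + sample(0:1, 1L)
        alt <- sample(setdiff(bases, coding_base(l)), 1L)
        sub_allele(l, alt)
      },
      intronic = {
        wide <- which(p$introns$end - p$introns$start >= 12L)
        if (!length(wide)) return(NULL)
        it <- p$introns[sample(rep(wide, 2L), 1L), ]
        l <- sample(seq.int(it$start + 4L, it$end - 5L), 1L)
        alt <- sample(setdiff(bases, coding_base(l)), 1L)
        sub_allele(l, alt)
      },
      five_prime_UTR = {
        hi <- p$u5 - 3L * p$ext_k - 2L
        if (hi < 2L) return(NULL)
        l <- sample(seq.int(1L, hi), 1L)
        alt <- sample(setdiff(bases, coding_base(l)), 1L)
        sub_allele(l, alt)
      },
      three_prime_UTR = {
        lo <- p$len - p$u3 + 2L
        hi <- p$len - 2L -
          (if (identical(p$pair_role, "A")) p$overlap_d + 2L else 0L)
        if (hi < lo) return(NULL)
        l <- sample(seq.int(lo, hi), 1L)
        alt <- sample(setdiff(bases, coding_base(l)), 1L)
        sub_allele(l, alt)
      },
      upstream = {
        off_bp <- sample(5:150, 1L)
        pos <- if (p$strand == "+") p$offset - off_bp else
          p$offset + p$len - 1L + off_bp
        ref <- base_at(chrom_seq[[p$chrom]], pos)
        tibble(chrom = p$chrom, pos = pos, ref = ref,
               alt = sample(setdiff(bases, ref), 1L),
               category = cat, gene_id = p$gene_id)
      },
      downstream = {
        off_bp <- sample(5:150, 1L)
        pos <- if (p$strand == "+") p$offset + p$len - 1L + off_bp else
          p$offset - off_bp
        ref <- base_at(chrom_seq[[p$chrom]], pos)
        tibble(chrom = p$chrom, pos = pos, ref = ref,
               alt = sample(setdiff(bases, ref), 1L),
               category = cat, gene_id = p$gene_id)
      },
      stop("unhandled category: ", cat)
    )
    if (!is.null(res)) return(res)
  }
}
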