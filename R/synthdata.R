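## Synthetic-data generator: genomes with planted proviruses plus ground
## truth, and U3 clone libraries with the group structure the downstream
## statistics assume (condition-dependent founder diversity).

LYMPHOID_ORGANS <- c("spleen", "thymus", "axillary_ln", "inguinal_ln",
                     "mesenteric_ln", "mandibular_ln",
                     "accessory_mandibular_ln", "superficial_parotid_ln",
                     "deep_cervical_ln")

## Evaluate code under a temporary seed, restoring the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## ---- founder U3 templates -------------------------------------------------

U3_CLASS_SIZES <- c(I = 615L, II = 556L, III = 440L, IV = 433L, V = 392L,
                    VI = 361L, VII = 346L)

## Feature copy layout per class, mirroring the seven-branch decision table.
U3_CLASS_LAYOUT <- list(
  I   = c("repeat_1", "repeat_1", "unique_2", "repeat_4", "repeat_5",
          "repeat_6", "repeat_6", "insertion_190"),
  II  = c("repeat_1", "repeat_1", "repeat_4", "repeat_5",
          "repeat_6", "repeat_6", "insertion_190"),
  III = c("repeat_1", "repeat_1", "unique_2", "repeat_4", "repeat_5",
          "repeat_5", "repeat_6", "repeat_6"),
  IV  = c("repeat_1", "repeat_1", "repeat_4", "repeat_4", "repeat_5",
          "repeat_5", "repeat_6"),
  V   = c("repeat_1", "repeat_1", "unique_2", "repeat_4", "repeat_5",
          "repeat_5", "repeat_6", "repeat_6"),
  VI  = c("repeat_1", "repeat_1", "repeat_5", "repeat_5",
          "repeat_6", "repeat_6"),
  VII = c("repeat_1", "repeat_1", "unique_2", "repeat_4", "repeat_4",
          "repeat_6", "repeat_6")
)

#' Founder U3 templates for the seven size classes
#'
#' Builds one deterministic U3 promoter template per branch class
#' (sizes 615, 556, 440, 433, 392, 361, 346 nt). Each template carries the
#' class's direct-repeat/unique-region copy layout from the tropism decision
#' table, a TATA box near the 3' end, and (classes I and II only) the 190-nt
#' insertion, with fixed pseudo-random filler bringing it to the class size.
#' Feature annotation therefore recovers the class profile by construction.
#'
#' @param feature_library Named feature sequences, see
#'   [load_feature_library()].
#' @param template_seed Seed for the fixed filler sequences; change it only
#'   to generate an unrelated template set.
#' @return Named character vector of templates (`I` ... `VII`).
#' @export
u3_templates <- function(feature_library = load_feature_library(),
                         template_seed = 1201L) {
  spacer_len <- 4L
  tail_len <- 12L
  with_seed(template_seed, {
    out <- vapply(names(U3_CLASS_SIZES), function(class) {
      elems <- feature_library[U3_CLASS_LAYOUT[[class]]]
      spacers <- replicate(length(elems) - 1L, random_dna(spacer_len))
      body <- paste0(elems[1L],
                     paste0(spacers, elems[-1L], collapse = ""))
      fixed_len <- nchar(body) + nchar(feature_library[["tata"]]) + tail_len
      filler_len <- U3_CLASS_SIZES[[class]] - fixed_len
      if (filler_len < 0) stop("feature library too long for class ", class)
      tpl <- paste0(body, random_dna(filler_len), feature_library[["tata"]],
                    random_dna(tail_len))
      stopifnot(nchar(tpl) == U3_CLASS_SIZES[[class]])
      tpl
    }, "")
    names(out) <- names(U3_CLASS_SIZES)
    out
  })
}

#' Founder template set with extra within-class variants
#'
#' The seven class templates plus `n_variants` additional founders, each a
#' fixed lightly substituted copy of one class template (named e.g.
#' `III.v1`). Variants stand in for the within-branch sequence variation of
#' a real clone library.
#'
#' @param n_variants Number of extra founders (default 1).
#' @param classes Classes to draw variants from (recycled).
#' @param n_subs Substitutions per variant (default 5).
#' @inheritParams u3_templates
#' @return Named character vector of founder sequences.
#' @export
u3_founders <- function(n_variants = 1L, classes = "III", n_subs = 5L,
                        feature_library = load_feature_library(),
                        template_seed = 1201L) {
  tpl <- u3_templates(feature_library, template_seed)
  if (n_variants == 0L) return(tpl)
  classes <- rep_len(classes, n_variants)
  vars <- with_seed(template_seed + 7L, {
    vapply(seq_len(n_variants), function(i) {
      base <- tpl[[classes[i]]]
      pos <- sample(nchar(base), n_subs)
      chars <- strsplit(base, "")[[1L]]
      for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
      paste(chars, collapse = "")
    }, "")
  })
  names(vars) <- paste0(classes, ".v", seq_len(n_variants))
  c(tpl, vars)
}

## ---- configuration --------------------------------------------------------

#' Default per-group clone-library specification
#'
#' Six specs (condition x cell type) totalling 260 clones, built so that the
#' realized library reproduces the structure the analysis assumes: the
#' burn-24h groups draw from fewer founder templates with skewed weights
#' (lower diversity than no-burn), and B-cell groups draw from fewer
#' founders than T-cell groups.
#'
#' @param clone_error_rate Per-bp substitution probability applied to each
#'   clone (default 0.001, which collapses ~260 clones to ~100 uniques at
#'   U3 lengths of 346-615 nt).
#' @return List of per-group spec lists (condition, cell_type, n_clones,
#'   founders, founder_weights, clone_error_rate).
#' @export
default_clone_library_spec <- function(clone_error_rate = 0.001) {
  spec <- function(condition, cell_type, n, founders, weights) {
    list(condition = condition, cell_type = cell_type, n_clones = n,
         founders = founders, founder_weights = weights / sum(weights),
         clone_error_rate = clone_error_rate)
  }
  all8 <- c("I", "II", "III", "IV", "V", "VI", "VII", "III.v1")
  list(
    spec("no_burn", "B", 45L, c("III", "VII", "I", "VI"),
         c(0.50, 0.25, 0.15, 0.10)),
    spec("no_burn", "T", 45L, all8,
         c(0.20, 0.15, 0.15, 0.12, 0.12, 0.10, 0.10, 0.06)),
    spec("burn_3h", "B", 45L, c("III", "VII", "I", "II"),
         c(0.40, 0.25, 0.20, 0.15)),
    spec("burn_3h", "T", 45L, all8,
         c(0.15, 0.15, 0.14, 0.14, 0.12, 0.10, 0.10, 0.10)),
    spec("burn_24h", "B", 40L, c("III", "VII"), c(0.85, 0.15)),
    spec("burn_24h", "T", 40L, c("III", "VII", "I"), c(0.70, 0.20, 0.10))
  )
}

#' Synthetic-data configuration
#'
#' @param seed Integer seed; fixed seed gives bit-identical outputs.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param n_proviruses Proviruses to plant (spread over chromosomes).
#' @param provirus_length_range Allowed planted provirus size in bp.
#' @param point_mutation_rate Per-bp substitution probability applied to the
#'   internal provirus body (between the LTRs).
#' @param ltr_divergence Per-bp substitution probability applied
#'   independently to each LTR copy (default 0: identical terminal LTRs, the
#'   hallmark of an intact provirus).
#' @param n_solo_ltrs Lone LTR copies planted as decoys (recombination
#'   relics that must not be called as proviruses).
#' @param clone_library Per-group clone specs,
#'   see [default_clone_library_spec()].
#' @param founder_templates Named founder U3 sequences (default
#'   [u3_founders()] with one class-III variant).
#' @param provirus_spec Optional data.frame overriding the per-provirus
#'   draws; columns among class, strand, pbs_type, gag, pol, env
#'   (status strings "intact"/"partial"/"defective").
#' @param feature_library,pbs_library,reference_model Sequence libraries and
#'   gene-cassette model shared with the annotation/mining stages.
#' @return Validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 1L,
                             chrom_length = 2e6,
                             n_proviruses = 10L,
                             provirus_length_range = c(5312L, 9054L),
                             point_mutation_rate = 0,
                             ltr_divergence = 0,
                             n_solo_ltrs = 0L,
                             clone_library = default_clone_library_spec(),
                             founder_templates = NULL,
                             provirus_spec = NULL,
                             feature_library = load_feature_library(),
                             pbs_library = load_pbs_library(),
                             reference_model = default_reference_model()) {
  if (is.null(founder_templates)) {
    founder_templates <- u3_founders(1L, "III",
                                     feature_library = feature_library)
  }
  rates <- c(point_mutation_rate, ltr_divergence)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0,1]", call. = FALSE)
  if (diff(provirus_length_range) < 0) stop("bad provirus_length_range")
  if (provirus_length_range[2] > chrom_length) {
    stop("provirus does not fit in chromosome", call. = FALSE)
  }
  for (sp in clone_library) {
    if (is.null(sp$n_clones) || sp$n_clones < 1) {
      stop("empty clone-library condition spec", call. = FALSE)
    }
    if (abs(sum(sp$founder_weights) - 1) > 1e-8) {
      stop("founder_weights must sum to 1", call. = FALSE)
    }
    if (!all(sp$founders %in% names(founder_templates))) {
      stop("unknown founder template in clone spec", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length, n_proviruses = n_proviruses,
                 provirus_length_range = provirus_length_range,
                 point_mutation_rate = point_mutation_rate,
                 ltr_divergence = ltr_divergence, n_solo_ltrs = n_solo_ltrs,
                 clone_library = clone_library,
                 founder_templates = founder_templates,
                 provirus_spec = provirus_spec,
                 feature_library = feature_library,
                 pbs_library = pbs_library,
                 reference_model = reference_model),
            class = "synthetic_config")
}

## ---- provirus construction ------------------------------------------------

#' Default gene-cassette reference model
#'
#' Expected peptide lengths of the three retroviral genes and the geometry
#' of the internal region: a leader between the primer-binding site and gag,
#' short inter-gene spacers, then gag / pol / env. The peptide lengths are
#' the canonical full-length MuLV polyprotein sizes; ORF integrity is judged
#' against them (intact >= 95%, partial 30-95%, defective < 30%).
#'
#' @param gag_aa,pol_aa,env_aa Reference peptide lengths (amino acids).
#' @param leader,spacer Leader and inter-gene spacer lengths (nt).
#' @param intact_min,partial_min Classification thresholds as fractions of
#'   the reference peptide length.
#' @return List used by the simulator and by [call_orfs()].
#' @export
default_reference_model <- function(gag_aa = 538L, pol_aa = 1196L,
                                    env_aa = 665L, leader = 60L,
                                    spacer = 15L, intact_min = 0.95,
                                    partial_min = 0.30) {
  list(gag_aa = gag_aa, pol_aa = pol_aa, env_aa = env_aa,
       leader = leader, spacer = spacer,
       intact_min = intact_min, partial_min = partial_min)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codons <- function(n) {
  if (n == 0) return(character(0))
  all3 <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                collapse = "")
  sense <- setdiff(all3, STOP_CODONS)
  sample(sense, n, replace = TRUE)
}

## Build one gene of reference peptide length aa with the requested coding
## status. Length is preserved; partial/defective genes carry planted
## premature stop codons (partial: one stop at ~50% of the peptide;
## defective: stops every ~10%).
make_gene <- function(aa, status = c("intact", "partial", "defective")) {
  status <- match.arg(status)
  codons <- c("ATG", random_codons(aa - 1L), "TAA")
  if (status == "partial") {
    codons[floor(aa * 0.5)] <- "TAA"
  } else if (status == "defective") {
    codons[pmax(2L, floor(aa * seq(0.1, 0.9, by = 0.1)))] <- "TAA"
  }
  paste(codons, collapse = "")
}

## Assemble one provirus construct (5'->3' on its own strand).
## Returns list(seq, ltr5, ltr3, layout).
build_provirus <- function(ltr, pbs_seq, statuses, target_size, model,
                           body_mutation_rate = 0, ltr_divergence = 0) {
  genes <- c(make_gene(model$gag_aa, statuses[["gag"]]),
             make_gene(model$pol_aa, statuses[["pol"]]),
             make_gene(model$env_aa, statuses[["env"]]))
  body <- paste0(random_dna(model$leader),
                 genes[1L], random_dna(model$spacer),
                 genes[2L], random_dna(model$spacer),
                 genes[3L])
  base <- 2L * nchar(ltr) + nchar(pbs_seq) + nchar(body)
  pad_min <- 40L
  if (base + pad_min > target_size) {
    stop("provirus cassette larger than target size", call. = FALSE)
  }
  pad <- target_size - base
  body <- paste0(body, random_dna(pad))
  internal <- paste0(pbs_seq, body)
  internal <- mutate_seq(internal, body_mutation_rate)
  ltr5 <- mutate_seq(ltr, ltr_divergence)
  ltr3 <- mutate_seq(ltr, ltr_divergence)
  list(seq = paste0(ltr5, internal, ltr3), ltr5 = ltr5, ltr3 = ltr3)
}

## ---- genome builder -------------------------------------------------------

#' Build a synthetic genome with planted proviruses and ground truth
#'
#' Each planted provirus is `LTR + PBS(18 nt) + leader + gag + pol + env +
#' padding + LTR` embedded in i.i.d. uniform background; the two LTR copies
#' are identical up to `ltr_divergence`. Minus-strand proviruses are stored
#' as the reverse complement, with the strand recorded in the truth table.
#' Coordinates are 1-based inclusive throughout.
#'
#' @param config A [synthetic_config()].
#' @return List with `genome` (named `DNAStringSet`), `truth` (data.frame:
#'   name, chrom, start, end, strand, size, class, ltr_length, pbs_type,
#'   gag, pol, env, ltr_identical) and `solo_ltrs` (data.frame of planted
#'   decoy LTRs, possibly empty).
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_proviruses
    classes_avail <- intersect(names(U3_CLASS_SIZES),
                               names(config$founder_templates))
    spec <- config$provirus_spec
    draw <- function(col, default) {
      if (!is.null(spec) && !is.null(spec[[col]])) rep_len(spec[[col]], n)
      else default
    }
    class <- draw("class", sample(classes_avail, n, replace = TRUE))
    strand <- draw("strand", sample(c("+", "-"), n, replace = TRUE))
    pbs_type <- draw("pbs_type",
                     sample(names(config$pbs_library), n, replace = TRUE,
                            prob = c(0.9, 0.1)[seq_along(config$pbs_library)]))
    st <- c("intact", "partial", "defective")
    gag <- draw("gag", sample(st, n, TRUE, prob = c(0.6, 0.2, 0.2)))
    pol <- draw("pol", sample(st, n, TRUE, prob = c(0.6, 0.2, 0.2)))
    env <- draw("env", sample(st, n, TRUE, prob = c(0.6, 0.2, 0.2)))

    model <- config$reference_model
    range <- config$provirus_length_range
    constructs <- vector("list", n)
    for (i in seq_len(n)) {
      ltr <- config$founder_templates[[class[i]]]
      base <- 2L * nchar(ltr) + 18L + model$leader +
        3L * (model$gag_aa + model$pol_aa + model$env_aa + 3L) +
        2L * model$spacer
      lo <- max(range[1], base + 40L)
      if (lo > range[2]) stop("provirus does not fit provirus_length_range",
                              call. = FALSE)
      target <- sample(seq(lo, range[2]), 1L)
      constructs[[i]] <- build_provirus(
        ltr, config$pbs_library[[pbs_type[i]]],
        c(gag = gag[i], pol = pol[i], env = env[i]),
        target, model, config$point_mutation_rate, config$ltr_divergence)
    }
    sizes <- vapply(constructs, function(x) nchar(x$seq), 0L)

    ## decoy solo LTRs
    n_solo <- config$n_solo_ltrs
    solo_class <- if (n_solo > 0) sample(classes_avail, n_solo, TRUE) else character(0)
    solo_seqs <- config$founder_templates[solo_class]

    ## place everything without overlap (1 kb margins)
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    assign_chr <- rep_len(chroms, n + n_solo)
    all_sizes <- c(sizes, nchar(solo_seqs))
    starts <- integer(n + n_solo)
    placed <- stats::setNames(vector("list", length(chroms)), chroms)
    margin <- 1000L
    for (i in seq_len(n + n_solo)) {
      chr <- assign_chr[i]
      size_i <- all_sizes[i]
      ok <- FALSE
      for (try in seq_len(1000L)) {
        s <- sample(seq(margin, config$chrom_length - size_i - margin), 1L)
        ivs <- placed[[chr]]
        clash <- any(vapply(ivs, function(iv) {
          s <= iv[2] + margin && (s + size_i - 1L) >= iv[1] - margin
        }, TRUE))
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place provirus; genome too crowded",
                    call. = FALSE)
      placed[[chr]] <- c(placed[[chr]], list(c(s, s + size_i - 1L)))
      starts[i] <- s
    }

    ## assemble chromosomes
    genome <- vapply(chroms, function(chr) random_dna(config$chrom_length), "")
    insert <- function(chr_seq, at, piece) {
      paste0(substr(chr_seq, 1L, at - 1L), piece,
             substr(chr_seq, at + nchar(piece), nchar(chr_seq)))
    }
    for (i in seq_len(n)) {
      piece <- constructs[[i]]$seq
      if (strand[i] == "-") piece <- revcomp(piece)
      genome[[assign_chr[i]]] <- insert(genome[[assign_chr[i]]], starts[i], piece)
    }
    solo_strand <- if (n_solo > 0) sample(c("+", "-"), n_solo, TRUE) else character(0)
    for (j in seq_len(n_solo)) {
      piece <- solo_seqs[[j]]
      if (solo_strand[j] == "-") piece <- revcomp(piece)
      genome[[assign_chr[n + j]]] <- insert(genome[[assign_chr[n + j]]],
                                            starts[n + j], piece)
    }
    stopifnot(all(nchar(genome) == config$chrom_length))

    truth <- data.frame(
      name = sprintf("ERV_%02d", seq_len(n)),
      chrom = assign_chr[seq_len(n)],
      start = starts[seq_len(n)],
      end = starts[seq_len(n)] + sizes - 1L,
      strand = strand,
      size = sizes,
      class = class,
      ltr_length = vapply(constructs, function(x) nchar(x$ltr5), 0L),
      pbs_type = pbs_type,
      gag = gag, pol = pol, env = env,
      ltr_identical = vapply(constructs,
                             function(x) identical(x$ltr5, x$ltr3), TRUE),
      stringsAsFactors = FALSE
    )
    truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    stopifnot(all(truth$end - truth$start + 1L == truth$size))

    solo <- data.frame(
      name = if (n_solo > 0) sprintf("soloLTR_%02d", seq_len(n_solo)) else character(0),
      chrom = assign_chr[seq_len(n_solo) + n],
      start = starts[seq_len(n_solo) + n],
      end = starts[seq_len(n_solo) + n] + nchar(solo_seqs) - 1L,
      strand = solo_strand,
      class = solo_class,
      stringsAsFactors = FALSE
    )
    dss <- Biostrings::DNAStringSet(genome)
    names(dss) <- chroms
    list(genome = dss, truth = truth, solo_ltrs = solo)
  })
}

## ---- clone library --------------------------------------------------------

#' Simulate a U3 clone library
#'
#' Clones are founder templates with rate-driven random substitutions,
#' drawn per experimental group according to the configured founder weights.
#' The default spec gives the burn-24h groups fewer founders with skewed
#' weights, so their realized nucleotide diversity is lower than the
#' no-burn groups (the downstream diversity statistics verify this
#' direction), and B-cell groups draw from fewer founders than T-cell
#' groups.
#'
#' @param config A [synthetic_config()].
#' @return U3 record data.frame (see [u3_records()]) with one row per clone.
#' @export
build_clone_library <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(config$clone_library) == 0) {
    stop("empty clone-library specification", call. = FALSE)
  }
  with_seed(config$seed + 104729L, {
    groups <- lapply(config$clone_library, function(sp) {
      founders <- sample(sp$founders, sp$n_clones, replace = TRUE,
                         prob = sp$founder_weights)
      seqs <- vapply(founders, function(f) {
        mutate_seq(config$founder_templates[[f]], sp$clone_error_rate)
      }, "")
      u3_records(
        id = sprintf("%s_%s_%03d", sp$condition, sp$cell_type,
                     seq_len(sp$n_clones)),
        sequence = unname(seqs),
        condition = sp$condition,
        cell_type = sp$cell_type,
        organ = sample(LYMPHOID_ORGANS, sp$n_clones, replace = TRUE)
      )
    })
    out <- do.call(rbind, groups)
    rownames(out) <- NULL
    out
  })
}

## ---- synthetic gene annotation -------------------------------------------

#' Build a synthetic gene annotation around planted proviruses
#'
#' Generates gene models (gene + exon features) for neighbor-gene mapping
#' tests: a configurable fraction of proviruses get a host gene wrapped
#' around them whose exons avoid the provirus (an intronic integration);
#' the rest of the genes are placed at random offsets, some within and some
#' beyond the flanking window.
#'
#' @param truth Truth table from [build_genome()].
#' @param chrom_length Chromosome length (recycled over chromosomes).
#' @param n_random_genes Unrelated genes to scatter per chromosome.
#' @param intronic Logical vector (recycled over proviruses): wrap this
#'   provirus in a host gene intron?
#' @param seed Integer seed.
#' @return `GRanges` with columns `type` (gene/exon), `gene_id`.
#' @export
build_gene_annotation <- function(truth, chrom_length, n_random_genes = 15L,
                                  intronic = c(TRUE, FALSE, FALSE),
                                  seed = 1L) {
  with_seed(seed, {
    recs <- list()
    add <- function(chrom, start, end, strand, type, gene_id) {
      recs[[length(recs) + 1L]] <<- data.frame(
        chrom = chrom, start = start, end = end, strand = strand,
        type = type, gene_id = gene_id, stringsAsFactors = FALSE)
    }
    intronic <- rep_len(intronic, nrow(truth))
    for (i in seq_len(nrow(truth))) {
      if (!intronic[i]) next
      gid <- paste0("hostgene_", truth$name[i])
      gs <- max(1L, truth$start[i] - 5000L)
      ge <- min(chrom_length, truth$end[i] + 5000L)
      add(truth$chrom[i], gs, ge, "+", "gene", gid)
      add(truth$chrom[i], gs, truth$start[i] - 2000L, "+", "exon", gid)
      add(truth$chrom[i], truth$end[i] + 2000L, ge, "+", "exon", gid)
    }
    for (chr in unique(truth$chrom)) {
      for (j in seq_len(n_random_genes)) {
        glen <- sample(2000:20000, 1L)
        gs <- sample(seq(1L, chrom_length - glen), 1L)
        gid <- sprintf("gene_%s_%02d", chr, j)
        strand <- sample(c("+", "-"), 1L)
        add(chr, gs, gs + glen - 1L, strand, "gene", gid)
        ## two exons at the gene ends
        elen <- max(200L, glen %/% 10L)
        add(chr, gs, gs + elen - 1L, strand, "exon", gid)
        add(chr, gs + glen - elen, gs + glen - 1L, strand, "exon", gid)
      }
    }
    df <- do.call(rbind, recs)
    gr <- GenomicRanges::GRanges(
      seqnames = df$chrom,
      ranges = IRanges::IRanges(df$start, df$end),
      strand = df$strand)
    S4Vectors::mcols(gr)$type <- df$type
    S4Vectors::mcols(gr)$gene_id <- df$gene_id
    gr
  })
}

## ---- writers --------------------------------------------------------------

#' Write simulator outputs to a directory
#'
#' Writes the genome FASTA, the truth TSV, a BED version of the truth
#' (0-based half-open), and the clone-library FASTA plus metadata TSV.
#'
#' @param sim Result of [build_genome()].
#' @param clones Result of [build_clone_library()] (optional).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, clones = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             truth = file.path(dir, "truth.tsv"),
             bed = file.path(dir, "truth.bed"))
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  bed <- data.frame(chrom = sim$truth$chrom, start = sim$truth$start - 1L,
                    end = sim$truth$end, name = sim$truth$name, score = 0L,
                    strand = sim$truth$strand)
  write.table(bed, paths[["bed"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(clones)) {
    paths <- c(paths, clones_fa = file.path(dir, "clones.fa"),
               clones_tsv = file.path(dir, "clones.tsv"))
    dss <- Biostrings::DNAStringSet(clones$sequence)
    names(dss) <- clones$id
    Biostrings::writeXStringSet(dss, paths[["clones_fa"]])
    write.table(clones[, c("id", "condition", "cell_type", "organ")],
                paths[["clones_tsv"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
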