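# Synthetic LAMP sequencing libraries with truth labels. The structural
# model is a simplification of real LAMP product (tandem alternating-
# orientation units, no cauliflower branching): downstream logic depends
# only on design-sequence order and target copies, which it preserves.

#' Synthetic background contig
#'
#' Uniform-random DNA generated from its own fixed seed (the session RNG is
#' saved and restored), so the same contig is reproducible independently of
#' any run seed. Stands in for a background genome at desk scale.
#'
#' @param length contig length in bp.
#' @param seed generation seed.
#' @return DNA string.
#' @export
synthetic_background <- function(length = 100000L, seed = 42L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  random_dna(length)
}

#' Synthetic sequencing-adapter sequence
#'
#' A fixed synthetic 70-mer standing in for an ONT rapid adapter (real
#' adapter sequences are supplied by configuration, never hard-coded into
#' the classifier).
#'
#' @return DNA string.
#' @export
synthetic_adapter <- function() {
  paste0("TCGATTCCGTTTGTAGTCGTCTGTACGGATCACCAGAAGGCTTAACCTGG",
         "ATCGTTCAGCAAGTTTCAGG")
}

#' Simulation configuration
#'
#' @param assay a [lamp_assay()].
#' @param n_reads number of reads to simulate.
#' @param true_vaf probability a target read carries the mutant allele.
#' @param mixture named class proportions over TARGET, FRAGMENT, SPURIOUS,
#'   BACKGROUND, ONT, SHORT, UNKNOWN; must sum to 1.
#' @param error_rates per-base substitution/insertion/deletion rates, each
#'   in [0, 0.5).
#' @param unit_geom_p geometric parameter of the unit-count distribution
#'   (`1 + Geom(p)` truncated to `[1, max_units]`).
#' @param max_units maximum units per concatemer.
#' @param arrival_rate Poisson read arrival rate, reads/second.
#' @param chimera_frac fraction of target reads made imbalanced: a long
#'   background section joined to a short (single-unit) target section.
#' @param background background contig (DNA string) used for BACKGROUND
#'   reads and chimeras.
#' @param adapter adapter sequence used for ONT reads.
#' @param rng_seed integer seed; identical seeds give byte-identical output.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(assay,
                              n_reads = 2000L,
                              true_vaf = 0.554,
                              mixture = c(TARGET = 0.45, FRAGMENT = 0.10,
                                          SPURIOUS = 0.15, BACKGROUND = 0.15,
                                          ONT = 0.05, SHORT = 0.05,
                                          UNKNOWN = 0.05),
                              error_rates = c(sub = 0.03, ins = 0.02,
                                              del = 0.02),
                              unit_geom_p = 0.45, max_units = 8L,
                              arrival_rate = 10, chimera_frac = 0,
                              background = synthetic_background(),
                              adapter = synthetic_adapter(),
                              rng_seed = 1L) {
  stopifnot(inherits(assay, "lamp_assay"))
  classes <- c("TARGET", "FRAGMENT", "SPURIOUS", "BACKGROUND", "ONT",
               "SHORT", "UNKNOWN")
  if (!all(names(mixture) %in% classes))
    stop("unknown class in mixture", call. = FALSE)
  if (abs(sum(mixture) - 1) > 1e-8)
    stop("mixture must sum to 1", call. = FALSE)
  if (any(error_rates < 0 | error_rates >= 0.5))
    stop("error rates must be in [0, 0.5)", call. = FALSE)
  if (n_reads < 0) stop("n_reads must be >= 0", call. = FALSE)
  if (true_vaf < 0 || true_vaf > 1) stop("true_vaf in [0,1]", call. = FALSE)
  structure(list(assay = assay, n_reads = as.integer(n_reads),
                 true_vaf = true_vaf, mixture = mixture,
                 error_rates = error_rates, unit_geom_p = unit_geom_p,
                 max_units = as.integer(max_units),
                 arrival_rate = arrival_rate, chimera_frac = chimera_frac,
                 background = background, adapter = adapter,
                 rng_seed = as.integer(rng_seed)), class = "sim_config")
}

# sequence of one layout token in read orientation
token_sequence <- function(token_label, token_strand, assay, allele = NULL) {
  if (token_label == "TARGET") {
    seed <- target_seed(assay)
    if (!is.null(allele)) {
      off <- assay$hotspot_pos - assay$target_span[1]
      substr(seed, off + 1L, off + 1L) <- allele
    }
    s <- seed
  } else {
    s <- assay$designs[[token_label]]
  }
  if (token_strand == "-") revcomp(s) else s
}

#' Simulate one error-free LAMP concatemer
#'
#' Alternating-orientation tandem copies of the core unit
#' (F2 F1 TARGET B1 B2 in reference orientation), with optional loop tokens
#' at unit junctions and outer primers at the ends, joined per the adjacency
#' grammar. Every emitted unit carries `allele` at the hotspot.
#'
#' @param assay a [lamp_assay()].
#' @param n_units number of units (>= 1).
#' @param allele hotspot base for every unit (default wildtype).
#' @param start_strand strand of the first unit.
#' @param loops,terminal include loop tokens / outer primers.
#' @return list: `sequence` (clean DNA), `units` (data.frame start, end,
#'   strand: 0-based half-open span of each unit's target seed on the
#'   emitted sequence), `layout` (token table).
#' @export
simulate_concatemer <- function(assay, n_units, allele = NULL,
                                start_strand = "+", loops = FALSE,
                                terminal = FALSE) {
  stopifnot(n_units >= 1, start_strand %in% c("+", "-"))
  allele <- allele %||% assay$wildtype_allele
  if (loops && !all(c("FLP", "BLP") %in% names(assay$designs)))
    loops <- FALSE
  ref <- assay$target_ref
  substr(ref, assay$hotspot_pos + 1L, assay$hotspot_pos + 1L) <- allele
  f2 <- locate_once(assay$designs[["F2"]], assay$target_ref, "F2")
  b2 <- locate_once(assay$designs[["B2"]], assay$target_ref, "B2")
  # a unit is a contiguous slice of the (allele-substituted) reference, so
  # error-free sub-reads align back at identity 1
  unit_fwd <- substr0(ref, f2[1], b2[2])
  U <- nchar(unit_fwd)
  seed_fwd <- assay$target_span - f2[1]
  seed_rev <- c(U - seed_fwd[2], U - seed_fwd[1])

  strands <- rep(c(start_strand, setdiff(c("+", "-"), start_strand)),
                 length.out = n_units)
  pieces <- character(0)
  is_unit <- logical(0)
  unit_strand <- character(0)
  for (k in seq_len(n_units)) {
    if (k > 1 && loops) {
      tok <- if (strands[k - 1] == "+") c("BLP", "-") else c("FLP", "+")
      pieces <- c(pieces, token_sequence(tok[1], tok[2], assay))
      is_unit <- c(is_unit, FALSE); unit_strand <- c(unit_strand, NA)
    }
    pieces <- c(pieces, if (strands[k] == "+") unit_fwd else revcomp(unit_fwd))
    is_unit <- c(is_unit, TRUE); unit_strand <- c(unit_strand, strands[k])
  }
  if (terminal) {
    f3 <- locate_once(assay$designs[["F3"]], assay$target_ref, "F3")
    b3 <- locate_once(assay$designs[["B3"]], assay$target_ref, "B3")
    lead <- if (strands[1] == "+") substr0(ref, f3[1], f2[1])
            else revcomp(substr0(ref, b2[2], b3[2]))
    trail <- if (strands[n_units] == "+") substr0(ref, b2[2], b3[2])
             else revcomp(substr0(ref, f3[1], f2[1]))
    pieces <- c(lead, pieces, trail)
    is_unit <- c(FALSE, is_unit, FALSE)
    unit_strand <- c(NA, unit_strand, NA)
  }
  ends <- cumsum(nchar(pieces))
  starts <- ends - nchar(pieces)
  idx <- which(is_unit)
  sd <- ifelse(unit_strand[idx] == "+", 1L, 0L)
  units <- data.frame(
    start = starts[idx] + ifelse(sd == 1L, seed_fwd[1], seed_rev[1]),
    end = starts[idx] + ifelse(sd == 1L, seed_fwd[2], seed_rev[2]),
    strand = unit_strand[idx])
  list(sequence = paste(pieces, collapse = ""), units = units,
       layout = concatemer_layout(n_units, start_strand, loops, terminal))
}

#' Apply an independent per-base error model
#'
#' Each base is independently deleted, substituted (to a uniformly chosen
#' other base), and/or followed by an inserted uniform base. Deterministic
#' under the session RNG seed.
#'
#' @param seq DNA string.
#' @param rates named numeric `c(sub=, ins=, del=)`, each in [0, 0.5).
#' @return list: `sequence` (noisy DNA), `map` (integer vector of length
#'   `nchar(seq) + 1`; `map[i+1]` is the emitted position of clean 0-based
#'   position `i`, so clean span `[a,b)` maps to `[map[a+1], map[b+1])`).
#' @export
corrupt_seq <- function(seq, rates = c(sub = 0.03, ins = 0.02, del = 0.02)) {
  if (any(rates < 0 | rates >= 0.5))
    stop("error rates must be in [0, 0.5)", call. = FALSE)
  n <- nchar(seq)
  if (n == 0 || sum(rates) == 0)
    return(list(sequence = seq, map = 0L:n))
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  alpha <- c("A", "C", "G", "T")
  del <- runif(n) < rates[["del"]]
  sub <- runif(n) < rates[["sub"]]
  ins <- runif(n) < rates[["ins"]]
  n_sub <- sum(sub & !del)
  if (n_sub) {
    cur <- bases[sub & !del]
    repl <- vapply(cur, function(b) sample(setdiff(alpha, b), 1L),
                   character(1), USE.NAMES = FALSE)
    bases[sub & !del] <- repl
  }
  out <- ifelse(del, "", bases)
  n_ins <- sum(ins)
  if (n_ins) out[ins] <- paste0(out[ins], sample(alpha, n_ins, replace = TRUE))
  contrib <- nchar(out)
  list(sequence = paste(out, collapse = ""),
       map = c(0L, cumsum(contrib)))
}

# one read of a given truth class; returns list(sequence, allele, n_units,
# unit_positions data.frame or NULL)
simulate_read <- function(class, cfg) {
  assay <- cfg$assay
  rates <- cfg$error_rates
  L <- nchar(assay$target_ref)
  hp <- assay$hotspot_pos
  noisy <- function(s) corrupt_seq(s, rates)
  res <- list(allele = NA_character_, n_units = NA_integer_, units = NULL)

  if (class == "TARGET") {
    n_units <- min(1L + rgeom(1, cfg$unit_geom_p), cfg$max_units)
    allele <- if (runif(1) < cfg$true_vaf) sample(assay$mutant_alleles, 1L)
              else assay$wildtype_allele
    sim <- simulate_concatemer(assay, n_units, allele,
                               start_strand = sample(c("+", "-"), 1L),
                               loops = runif(1) < 0.5,
                               terminal = runif(1) < 0.5)
    clean <- sim$sequence
    offset <- 0L
    if (cfg$chimera_frac > 0 && runif(1) < cfg$chimera_frac) {
      # imbalanced concatemer: long background section + short (1-unit)
      # target section
      one <- simulate_concatemer(assay, 1L, allele,
                                 start_strand = sample(c("+", "-"), 1L))
      bglen <- sample1(400:900)
      bg <- slice_background(cfg$background, bglen)
      if (runif(1) < 0.5) {
        clean <- paste0(bg, one$sequence); offset <- nchar(bg)
      } else {
        clean <- paste0(one$sequence, bg); offset <- 0L
      }
      sim <- one
    }
    nz <- noisy(clean)
    units <- sim$units
    units$start <- nz$map[units$start + offset + 1L]
    units$end <- nz$map[units$end + offset + 1L]
    return(list(allele = allele, n_units = nrow(units), units = units,
                sequence = nz$sequence))
  }

  if (class == "FRAGMENT") {
    left_avail <- hp - 3L
    right_lo <- hp + 4L
    use_left <- runif(1) < 0.5 && left_avail >= 64L
    if (use_left) {
      len <- sample1(64L:min(170L, left_avail))
      start <- sample1(0L:(left_avail - len))
    } else {
      avail <- L - right_lo
      len <- sample1(64L:min(170L, avail))
      start <- sample1(right_lo:(L - len))
    }
    s <- substr0(assay$target_ref, start, start + len)
    if (runif(1) < 0.5) s <- revcomp(s)
    return(list(allele = NA_character_, n_units = NA_integer_, units = NULL,
                sequence = noisy(s)$sequence))
  }

  if (class == "SPURIOUS") {
    labs <- names(assay$designs)
    repeat {
      k <- sample1(3:8)
      pick <- sample(labs, k, replace = TRUE)
      str <- sample(c("+", "-"), k, replace = TRUE)
      s <- paste(mapply(token_sequence, pick, str,
                        MoreArgs = list(assay = assay)), collapse = "")
      if (nchar(s) >= 65L) break
    }
    return(list(allele = NA_character_, n_units = NA_integer_, units = NULL,
                sequence = noisy(s)$sequence))
  }

  if (class == "BACKGROUND") {
    s <- slice_background(cfg$background, sample1(100:1000))
    return(list(allele = NA_character_, n_units = NA_integer_, units = NULL,
                sequence = noisy(s)$sequence))
  }

  if (class == "ONT") {
    return(list(allele = NA_character_, n_units = NA_integer_, units = NULL,
                sequence = noisy(cfg$adapter)$sequence))
  }

  if (class == "SHORT") {
    return(list(allele = NA_character_, n_units = NA_integer_, units = NULL,
                sequence = random_dna(sample1(20:52))))
  }

  # UNKNOWN: random DNA unrelated to assay and background
  list(allele = NA_character_, n_units = NA_integer_, units = NULL,
       sequence = random_dna(sample1(100:500)))
}

slice_background <- function(bg, len) {
  len <- min(len, nchar(bg))
  start <- sample1(0:(nchar(bg) - len))
  s <- substr0(bg, start, start + len)
  if (runif(1) < 0.5) revcomp(s) else s
}

#' Simulate a sequencing run
#'
#' Draws `n_reads` reads from the class mixture, assigns Poisson arrival
#' times, and optionally writes a FASTQ (with ISO-8601 `start_time=` header
#' metadata) and a truth TSV. Identical seeds give byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param fastq optional FASTQ output path.
#' @param truth optional truth TSV output path.
#' @param t0 run origin timestamp (POSIXct, UTC).
#' @return data.frame with one row per read: `read_id`, `class` (truth),
#'   `allele`, `n_units`, `unit_positions` (semicolon-separated
#'   `start-end:strand`), `start_time` (seconds since run start),
#'   `sequence`.
#' @export
simulate_run <- function(config, fastq = NULL, truth = NULL,
                         t0 = as.POSIXct("2022-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_reads
  classes <- if (n > 0)
    sample(names(config$mixture), n, replace = TRUE, prob = config$mixture)
  else character(0)
  times <- cumsum(rexp(n, config$arrival_rate))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- simulate_read(classes[i], config)
    up <- if (!is.null(r$units) && nrow(r$units))
      paste(sprintf("%d-%d:%s", r$units$start, r$units$end, r$units$strand),
            collapse = ";")
    else ""
    rows[[i]] <- data.frame(
      read_id = sprintf("read%06d", i), class = classes[i],
      allele = r$allele %||% NA_character_,
      n_units = r$n_units %||% NA_integer_,
      unit_positions = up, start_time = times[i], sequence = r$sequence,
      stringsAsFactors = FALSE)
  }
  out <- if (n > 0) do.call(rbind, rows) else
    data.frame(read_id = character(), class = character(),
               allele = character(), n_units = integer(),
               unit_positions = character(), start_time = numeric(),
               sequence = character(), stringsAsFactors = FALSE)

  if (!is.null(fastq)) {
    old <- options(digits.secs = 3); on.exit(options(old), add = TRUE)
    stamp <- format(t0 + out$start_time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
    qual <- vapply(nchar(out$sequence), function(l) strrep("-", l),
                   character(1))
    lines <- as.vector(rbind(
      sprintf("@%s start_time=%s", out$read_id, stamp),
      out$sequence, "+", qual))
    writeLines(lines, fastq)
  }
  if (!is.null(truth)) {
    write.table(out[, setdiff(names(out), "sequence")], truth, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}
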