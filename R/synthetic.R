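#' Intensity model for MSY array probes
#'
#' The generative model behind the synthetic cohorts: each probe's log2
#' ratio is Gaussian with a mean set by its copy state and a shared noise
#' sd.  The default means are the three calibration anchors printed for
#' this platform: -0.47 for single-copy male sequence, -2.02 for absent
#' sequence (female background), 0.04 for duplicated sequence.  A few MSY
#' intervals cross-hybridise in females; inside `female_hot_regions`
#' zero-copy probes use the elevated `hot_mean` instead.
#'
#' @param mu_zero_copy,mu_one_copy,mu_two_copy State means (log2 ratio);
#'   must be ordered `mu_zero_copy < mu_one_copy < mu_two_copy`.
#' @param sigma Per-probe noise sd (> 0).  The source data publish no
#'   per-probe variance; 0.25 is the package default and is exposed here.
#' @param female_hot_regions Tibble (`start`, `stop`) of elevated-background
#'   intervals; the default mirrors the three such regions reported for
#'   this platform, at coordinates inside the bundled MSY span but outside
#'   every catalogued CNV region.
#' @param hot_mean Mean for zero-copy probes inside hot regions
#'   (default -0.3).
#' @return A list of class `ycnv_intensity_model`.
#' @export
intensity_model <- function(mu_zero_copy = -2.02,
                            mu_one_copy = -0.47,
                            mu_two_copy = 0.04,
                            sigma = 0.25,
                            female_hot_regions = default_hot_regions(),
                            hot_mean = -0.3) {
  if (!(mu_zero_copy < mu_one_copy && mu_one_copy < mu_two_copy)) {
    abort("State means must be ordered: mu_zero_copy < mu_one_copy < mu_two_copy.")
  }
  if (sigma <= 0) abort("`sigma` must be > 0.")
  structure(list(mu_zero_copy = mu_zero_copy,
                 mu_one_copy = mu_one_copy,
                 mu_two_copy = mu_two_copy,
                 sigma = sigma,
                 female_hot_regions = female_hot_regions,
                 hot_mean = hot_mean),
            class = "ycnv_intensity_model")
}

#' @rdname intensity_model
#' @export
default_hot_regions <- function() {
  tibble(start = c(3200000, 8000000, 13000000),
         stop = c(3450000, 8250000, 13250000))
}

#' Generate a synthetic MSY probe manifest
#'
#' Evenly spaced probes over an MSY-like span (2.7-28.0 Mb), with SNP
#' probes interleaved among CN probes in the array's 288:7891 proportion.
#' The default size matches the real array's 8179 MSY probes, giving the
#' bundled region map the probe support per region that the pattern
#' classifier assumes; smaller manifests (same map) are useful for fast
#' tests.
#'
#' @param n_probes Number of probes (default 8179).
#' @param span Length-2 numeric, chrY bp range (default `c(2.7e6, 2.8e7)`).
#' @param n_snp Number of SNP-class probes (default scaled as 288/8179).
#' @return A probe manifest tibble.
#' @export
synthetic_manifest <- function(n_probes = 8179,
                               span = msy_span(),
                               n_snp = round(n_probes * 288 / 8179)) {
  pos <- round(seq(span[1], span[2], length.out = n_probes))
  cls <- rep("CN", n_probes)
  if (n_snp > 0) {
    cls[round(seq(1, n_probes, length.out = n_snp))] <- "SNP"
  }
  probe_manifest(sprintf("probe_%05d", seq_len(n_probes)), pos, cls)
}

#' Simulate one sample's intensity profile
#'
#' Draws each probe's log2 ratio from the intensity model: a male baseline
#' is single copy across the MSY, a female is zero copies; `events`
#' override the baseline (deletions to zero copies, duplications to two),
#' and zero-copy probes inside the model's hot regions use the elevated
#' background mean.  Identical inputs and seed give identical output.
#'
#' @param manifest Probe manifest.
#' @param model [intensity_model()].
#' @param sex `"male"` or `"female"`.
#' @param events Tibble (`kind` in `{"deletion","duplication"}`, `start`,
#'   `stop` in bp) or NULL.  Events must lie inside the manifest span.
#' @param seed Integer seed.
#' @return Numeric log2-ratio vector aligned to the manifest.
#' @export
simulate_profile <- function(manifest, model = intensity_model(),
                             sex = c("male", "female"),
                             events = NULL, seed = 1) {
  sex <- arg_match(sex)
  n <- nrow(manifest)
  state <- rep(if (sex == "male") 1L else 0L, n)
  if (!is.null(events) && nrow(events) > 0L) {
    span <- range(manifest$position)
    for (i in seq_len(nrow(events))) {
      if (events$start[i] > events$stop[i]) {
        abort(sprintf("Event %d has start > stop.", i))
      }
      if (events$stop[i] < span[1] || events$start[i] > span[2]) {
        abort(sprintf("Event %d [%s, %s] lies outside the manifest span [%s, %s].",
                      i, format(events$start[i], scientific = FALSE),
                      format(events$stop[i], scientific = FALSE),
                      format(span[1], scientific = FALSE),
                      format(span[2], scientific = FALSE)))
      }
      idx <- region_probe_idx(manifest, events$start[i], events$stop[i])
      state[idx] <- if (events$kind[i] == "deletion") 0L else 2L
    }
  }
  mu <- c(model$mu_zero_copy, model$mu_one_copy, model$mu_two_copy)[state + 1L]
  hot <- rep(FALSE, n)
  hr <- model$female_hot_regions
  if (!is.null(hr) && nrow(hr) > 0L) {
    for (i in seq_len(nrow(hr))) {
      hot[region_probe_idx(manifest, hr$start[i], hr$stop[i])] <- TRUE
    }
  }
  mu[state == 0L & hot] <- model$hot_mean
  withr::with_seed(seed, rnorm(n, mean = mu, sd = model$sigma))
}

#' Events implied by a catalogued pattern
#'
#' Converts a pattern's region-state signature into concrete CNV events:
#' each required `del`/`dup` region becomes an interval, and overlapping or
#' adjacent intervals of the same kind are merged.  Wildcard (`any`)
#' requirements generate no event.
#'
#' @param pattern Pattern name present in `catalog`.
#' @param catalog Catalog tibble (default [default_pattern_catalog()]).
#' @param region_map Region map the catalog refers to.
#' @return Event tibble (`kind`, `start`, `stop`, `pattern_name`).
#' @export
pattern_events <- function(pattern, catalog = default_pattern_catalog(),
                           region_map = default_region_map()) {
  sig <- catalog %>% filter(.data$pattern == !!pattern, .data$state != "any")
  if (nrow(sig) == 0L) {
    abort(sprintf("Pattern \"%s\" is not in the catalog.", pattern))
  }
  sig <- sig %>%
    left_join(region_map[, c("region", "start", "stop")], by = "region") %>%
    mutate(kind = ifelse(.data$state == "del", "deletion", "duplication")) %>%
    arrange(.data$start)
  out <- purrr::map_dfr(c("deletion", "duplication"), function(k) {
    iv <- sig %>% filter(.data$kind == k)
    if (nrow(iv) == 0L) return(NULL)
    merged <- list()
    cur <- c(iv$start[1], iv$stop[1])
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$start[i] <= cur[2] + 1) {
        cur[2] <- max(cur[2], iv$stop[i])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- c(iv$start[i], iv$stop[i])
      }
    }
    merged[[length(merged) + 1L]] <- cur
    tibble(kind = k,
           start = purrr::map_dbl(merged, 1L),
           stop = purrr::map_dbl(merged, 2L))
  })
  out$pattern_name <- pattern
  out %>% arrange(.data$start)
}

# shift event boundaries by up to `jitter_probes` probe spacings, emulating
# the similar-but-not-identical breakpoints of recurrent duplications
jitter_events <- function(events, manifest, jitter_probes) {
  if (jitter_probes <= 0 || nrow(events) == 0L) return(events)
  spacing <- stats::median(diff(manifest$position))
  span <- range(manifest$position)
  shift <- function(x) {
    x + sample(seq(-jitter_probes, jitter_probes), length(x), replace = TRUE) * spacing
  }
  events %>%
    mutate(start = pmax(span[1], shift(.data$start)),
           stop = pmin(span[2], shift(.data$stop))) %>%
    filter(.data$start < .data$stop)
}

#' Simulate Y-SNP genotypes for a haplogroup
#'
#' Generates the allele calls an individual of the given clade would show
#' on the tree's SNP panel: the derived allele at every SNP defining a node
#' on the root-to-clade path, the ancestral allele elsewhere, with each
#' call independently masked as missing (`NA`) at `missing_rate`.  SNPs
#' defining the clade's children stay ancestral, which is what later allows
#' exclusion calls such as `NO-M214(xM175)`.
#'
#' @param tree A `ytree` (see [read_ytree()]).
#' @param haplogroup Node name in the tree.
#' @param missing_rate Per-call missing probability (default 0).
#' @param seed Integer seed.
#' @return Tibble (`snp_id`, `allele`); `allele` is `NA` when missing.
#' @export
simulate_genotypes <- function(tree, haplogroup, missing_rate = 0, seed = 1) {
  path <- ytree_path(tree, haplogroup)
  snps <- tree$snps
  derived <- snps$node %in% path
  allele <- ifelse(derived, snps$derived, snps$ancestral)
  if (missing_rate > 0) {
    allele <- withr::with_seed(seed, {
      miss <- runif(length(allele)) < missing_rate
      replace(allele, miss, NA_character_)
    })
  }
  tibble(snp_id = snps$snp_id, allele = allele)
}

#' Cohort configuration for the synthetic generator
#'
#' Describes the study conditions a simulated cohort reproduces: how many
#' males per major haplogroup, the per-haplogroup probabilities of carrying
#' each catalogued CNV pattern, the number of background females for QC,
#' the intensity model and the probe manifest.  The defaults replay the
#' published survey: the 12 major-haplogroup sample sizes (1506 males in
#' total), per-haplogroup pattern frequencies derived from the printed
#' carrier counts (the ten haplogroup-enriched patterns at their printed
#' per-haplogroup frequencies; each haplogroup's remaining carrier mass
#' spread evenly over the other catalogued patterns), 61 females, and a
#' genotype missing rate of 0.1.
#'
#' @param counts Named integer vector: males per haplogroup (names are
#'   display labels such as `"NO-M214(xM175)"`).
#' @param pattern_freqs Named list: for each haplogroup, a named numeric
#'   vector of per-pattern carrier probabilities (must sum to <= 1; the
#'   remainder is the probability of carrying no CNV).
#' @param n_females Background females simulated for the QC stage.
#' @param manifest,model,catalog,region_map,tree Pipeline inputs; `catalog`,
#'   `region_map` and `tree` may also be file paths, read with
#'   [read_pattern_catalog()], [read_region_map()] and [read_ytree()] —
#'   a missing file fails here, before any computation starts.
#' @param missing_rate Genotype missing rate (see [simulate_genotypes()]).
#' @param jitter_probes Breakpoint jitter in probes applied to each event
#'   (default 2).
#' @return A list of class `ycnv_cohort_config`.
#' @export
cohort_config <- function(counts = NULL,
                          pattern_freqs = NULL,
                          n_females = 61,
                          manifest = synthetic_manifest(),
                          model = intensity_model(),
                          catalog = default_pattern_catalog(),
                          region_map = default_region_map(),
                          tree = default_ytree(),
                          missing_rate = 0.1,
                          jitter_probes = 2) {
  as_path <- function(x, what) {
    if (!is.character(x)) return(x)
    if (!file.exists(x)) abort(sprintf("%s file not found: %s", what, x))
    x
  }
  region_map <- as_path(region_map, "Region map")
  if (is.character(region_map)) region_map <- read_region_map(region_map)
  catalog <- as_path(catalog, "Catalog")
  if (is.character(catalog)) catalog <- read_pattern_catalog(catalog, region_map)
  tree <- as_path(tree, "Tree")
  if (is.character(tree)) tree <- read_ytree(tree)
  if (is.character(manifest)) manifest <- read_probe_manifest(as_path(manifest, "Manifest"))
  if (is.null(counts) || is.null(pattern_freqs)) {
    ref <- reference_cohort_frequencies(catalog)
    counts <- counts %||% ref$counts
    pattern_freqs <- pattern_freqs %||% ref$pattern_freqs
  }
  for (h in names(pattern_freqs)) {
    p <- pattern_freqs[[h]]
    if (any(p < 0)) abort(sprintf("Negative pattern probability for haplogroup %s.", h))
    if (sum(p) > 1 + 1e-9) {
      abort(sprintf("Pattern probabilities for haplogroup %s sum to %.3f > 1.", h, sum(p)))
    }
    unknown <- setdiff(names(p), unique(catalog$pattern))
    if (length(unknown) > 0L) {
      abort(sprintf("Unknown pattern(s) for haplogroup %s: %s", h,
                    paste(unknown, collapse = ", ")))
    }
  }
  miss <- setdiff(names(counts), names(pattern_freqs))
  if (length(miss) > 0L) {
    pattern_freqs[miss] <- list(setNames(numeric(0), character(0)))
  }
  structure(list(counts = counts, pattern_freqs = pattern_freqs,
                 n_females = n_females, manifest = manifest, model = model,
                 catalog = catalog, region_map = region_map, tree = tree,
                 missing_rate = missing_rate, jitter_probes = jitter_probes),
            class = "ycnv_cohort_config")
}

# per-haplogroup sizes and pattern frequencies replaying the bundled
# published survey tables
reference_cohort_frequencies <- function(catalog = default_pattern_catalog()) {
  var_counts <- ycnv_example_counts("variants")
  any_counts <- ycnv_example_counts("carriers")
  variants <- setdiff(names(var_counts), c("haplogroup", "n"))
  counts <- setNames(any_counts$n, any_counts$haplogroup)
  other_patterns <- setdiff(unique(catalog$pattern), variants)
  freqs <- lapply(any_counts$haplogroup, function(h) {
    n <- counts[[h]]
    vrow <- var_counts[var_counts$haplogroup == h, variants, drop = FALSE]
    enr <- setNames(as.numeric(vrow[1, ]), variants) / n
    rest_carriers <- any_counts$carriers[any_counts$haplogroup == h] -
      sum(as.numeric(vrow[1, ]))
    rest <- setNames(rep(max(0, rest_carriers) / n / length(other_patterns),
                         length(other_patterns)), other_patterns)
    p <- c(enr, rest)
    p[p > 0]
  })
  list(counts = counts, pattern_freqs = setNames(freqs, any_counts$haplogroup))
}

#' Simulate a full cohort
#'
#' Draws, for every male, a CNV pattern (or none) from his haplogroup's
#' pattern distribution, implants the pattern's events with breakpoint
#' jitter, simulates the intensity profile, and generates Y-SNP genotypes
#' consistent with his clade; background females are simulated for the QC
#' stage.  The whole procedure is a deterministic function of
#' `(config, seed)`.
#'
#' @param config [cohort_config()].
#' @param seed Integer seed.
#' @return A list: `intensities` (probes x samples matrix, males then
#'   females), `truth` (sample, sex, haplogroup, pattern, seed), `events`
#'   (implanted events per sample), `genotypes` (sample, snp_id, allele),
#'   plus the manifest and config.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  withr::with_seed(seed, {
    manifest <- config$manifest
    hgs <- names(config$counts)
    truth <- purrr::map_dfr(hgs, function(h) {
      n <- config$counts[[h]]
      if (n == 0L) return(NULL)
      p <- config$pattern_freqs[[h]]
      pattern <- if (length(p) == 0L) rep("none", n) else {
        sample(c(names(p), "none"), n, replace = TRUE, prob = c(p, 1 - sum(p)))
      }
      tibble(haplogroup = h, pattern = pattern)
    })
    n_m <- nrow(truth)
    truth <- truth %>%
      mutate(sample = sprintf("M%04d", row_number()), sex = "male", .before = 1L)
    events <- purrr::map_dfr(seq_len(n_m), function(i) {
      if (truth$pattern[i] == "none") return(NULL)
      ev <- pattern_events(truth$pattern[i], config$catalog, config$region_map)
      ev <- jitter_events(ev, manifest, config$jitter_probes)
      dplyr::bind_cols(tibble(sample = truth$sample[i]), ev)
    })
    profile_seeds <- sample.int(.Machine$integer.max - 1L, n_m + config$n_females)
    males <- vapply(seq_len(n_m), function(i) {
      ev <- events %>% filter(.data$sample == truth$sample[i])
      simulate_profile(manifest, config$model, "male",
                       events = if (nrow(ev)) ev else NULL,
                       seed = profile_seeds[i])
    }, numeric(nrow(manifest)))
    females <- if (config$n_females > 0L) {
      vapply(seq_len(config$n_females), function(i) {
        simulate_profile(manifest, config$model, "female",
                         seed = profile_seeds[n_m + i])
      }, numeric(nrow(manifest)))
    } else {
      matrix(numeric(0), nrow = nrow(manifest), ncol = 0)
    }
    intensities <- cbind(males, females)
    fem_ids <- if (config$n_females > 0L) sprintf("F%03d", seq_len(config$n_females)) else character(0)
    colnames(intensities) <- c(truth$sample, fem_ids)
    rownames(intensities) <- manifest$probe_id
    geno_seeds <- sample.int(.Machine$integer.max - 1L, n_m)
    genotypes <- purrr::map_dfr(seq_len(n_m), function(i) {
      node <- sub("\\(x.*\\)$", "", truth$haplogroup[i])
      g <- simulate_genotypes(config$tree, node, config$missing_rate, geno_seeds[i])
      dplyr::bind_cols(tibble(sample = truth$sample[i]), g)
    })
    truth <- bind_rows(truth,
                       tibble(sample = fem_ids, sex = "female",
                              haplogroup = NA_character_, pattern = "none"))
    truth$seed <- seed
    list(intensities = intensities, truth = truth, events = events,
         genotypes = genotypes, manifest = manifest, config = config)
  })
}
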