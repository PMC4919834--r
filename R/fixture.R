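## Deterministic fixture generator: emulates realistic log documents
## (module lists with versions/paths/checksums, system and timing records)
## and controlled perturbations between pairs of documents, so the format,
## parser and diff are testable with no external data.

RI_PERTURB_CATEGORIES <- c("module-version", "module-checksum",
                           "module-added", "module-removed", "interpreter",
                           "system", "search-path", "user", "program",
                           "args", "exit-status", "extra")

#' Fixture specification
#'
#' @param seed Integer seed; identical specs yield byte-identical rendered
#'   fixtures.
#' @param n_modules Number of synthetic `MODULE` records (>= 0).
#' @param n_processors Number of `PROC` records (>= 1).
#' @param perturbations List of perturbations to apply to a second derived
#'   document; each element is a category string or a
#'   `list(category =, name =)` pair (the name selects a module for the
#'   `module-*` categories).
#' @return A `runinfo_fixture_spec`.
#' @export
fixture_spec <- function(seed, n_modules = 8L, n_processors = 2L,
                         perturbations = list()) {
  seed <- as.integer(seed)
  n_modules <- as.integer(n_modules)
  n_processors <- as.integer(n_processors)
  stopifnot(length(seed) == 1L, !is.na(seed),
            n_modules >= 0L, n_processors >= 1L)
  perturbations <- lapply(perturbations, function(p) {
    if (is.character(p)) p <- list(category = p)
    if (is.null(p$category)) {
      stop("perturbation must have a category")
    }
    p
  })
  structure(
    list(seed = seed, n_modules = n_modules, n_processors = n_processors,
         perturbations = perturbations),
    class = "runinfo_fixture_spec"
  )
}

ri_syllables <- c("al", "be", "cor", "dex", "fen", "gly", "hom", "ix",
                  "jun", "kap", "lim", "mer", "nov", "oct", "pra", "quo",
                  "ril", "sep", "tul", "vex")

ri_rand_name <- function() {
  paste0(paste(sample(ri_syllables, sample(2:3, 1)), collapse = ""),
         sample(c("", "lib", "kit", "seq", "db"), 1))
}

ri_rand_version <- function() {
  sprintf("%d.%d.%d", sample(0:9, 1), sample(0:20, 1), sample(0:9, 1))
}

ri_rand_hex <- function(n = RI_DIGEST_NCHAR) {
  paste(sample(c(as.character(0:9), letters[1:6]), n, replace = TRUE),
        collapse = "")
}

ri_distinct_names <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, replicate(n, ri_rand_name())))
  }
  sort(out[seq_len(n)], method = "radix")
}

## the synthetic "scene": snapshot objects a document is built from
ri_fixture_scene <- function(spec) {
  base_time <- as.POSIXct("2016-06-24 10:11:12", tz = "UTC")
  mod_names <- ri_distinct_names(spec$n_modules)
  modules <- lapply(mod_names, function(nm) {
    module_record(nm, ri_rand_version(),
                  file.path("/opt/site/lib", paste0(nm, ".r")),
                  ri_rand_hex())
  })
  search_path <- snapshot_search_path(c(
    "/opt/site/lib",
    sprintf("/home/worker/lib/v%d", sample(1:9, 1)),
    "/usr/lib/lang/library"
  ))
  processors <- replicate(spec$n_processors, c(
    model = sprintf("GenericCPU model %d", sample(1000:9999, 1)),
    cores = as.character(sample(c(2L, 4L, 8L, 16L), 1)),
    mhz = sprintf("%.3f", stats::runif(1, 1200, 3600))
  ), simplify = FALSE)
  system <- system_info(
    os_name = "Linux",
    node_name = sprintf("node%02d", sample(1:99, 1)),
    os_release = sprintf("5.%d.%d-generic", sample(0:19, 1), sample(0:99, 1)),
    os_version = sprintf("#%d SMP PREEMPT_DYNAMIC", sample(1:200, 1)),
    machine = "x86_64",
    processors = processors,
    total_memory_bytes = sample(c(8, 16, 32, 64), 1) * 2^30
  )
  interpreter <- interpreter_info(
    executable_path = "/usr/lib/lang/bin/exec/lang",
    version = sprintf("lang version %d.%d.%d", sample(3:5, 1),
                      sample(0:9, 1), sample(0:9, 1)),
    checksum = ri_rand_hex(),
    libc_version = sprintf("glibc 2.%d", sample(17:39, 1)),
    libc_checksum = ri_rand_hex()
  )
  uid <- sample(1000:1999, 1)
  user <- user_context(
    effective_user = sprintf("%d(worker%d)", uid, uid %% 10),
    effective_groups = c(sprintf("%d(worker%d)", uid, uid %% 10),
                         "100(users)")
  )
  start <- base_time + sample(0:86400, 1)
  program <- snapshot_program(
    argv = if (sample(0:3, 1) == 0L) character(0) else {
      c("--input", sprintf("run%d.dat", sample(1:50, 1)))
    },
    main_path = NA_character_
  )
  ## snapshot_program cannot see a synthetic file; fill identity directly
  program$directory <- "/opt/pipelines"
  program$name <- paste0(ri_rand_name(), ".r")
  program$declared_version <- ri_rand_version()
  program$checksum <- ri_rand_hex()
  window <- finalize_window(start, start + round(stats::runif(1, 1, 5000), 3), 0L)
  list(modules = modules, search_path = search_path, system = system,
       interpreter = interpreter, user = user, program = program,
       window = window, extra = list())
}

ri_scene_document <- function(sc) {
  build_document(sc$modules, sc$search_path, sc$system, sc$interpreter,
                 sc$user, sc$program, sc$window, sc$extra)
}

ri_pick_module <- function(sc, name) {
  nms <- vapply(sc$modules, function(m) m$name, character(1))
  if (!is.null(name)) {
    i <- match(name, nms)
    if (is.na(i)) {
      stop("perturbation names unknown module: ", name)
    }
    return(i)
  }
  if (length(nms) == 0L) {
    stop("cannot perturb modules of a fixture with n_modules = 0")
  }
  sample(seq_along(nms), 1)
}

ri_apply_perturbation <- function(sc, p) {
  cat_ <- p$category
  name <- p$name
  switch(cat_,
    "module-version" = {
      i <- ri_pick_module(sc, name)
      m <- sc$modules[[i]]
      repeat {
        v <- ri_rand_version()
        if (!identical(v, m$version)) break
      }
      sc$modules[[i]]$version <- v
    },
    "module-checksum" = {
      i <- ri_pick_module(sc, name)
      sc$modules[[i]]$checksum <- ri_rand_hex()
    },
    "module-added" = {
      nms <- vapply(sc$modules, function(m) m$name, character(1))
      repeat {
        nm <- if (is.null(name)) ri_rand_name() else name
        if (!nm %in% nms) break
        if (!is.null(name)) stop("module-added name already present: ", name)
      }
      newm <- module_record(nm, ri_rand_version(),
                            file.path("/opt/site/lib", paste0(nm, ".r")),
                            ri_rand_hex())
      sc$modules <- append(sc$modules, list(newm))
      ord <- order(vapply(sc$modules, function(m) m$name, character(1)),
                   method = "radix")
      sc$modules <- sc$modules[ord]
    },
    "module-removed" = {
      i <- ri_pick_module(sc, name)
      sc$modules <- sc$modules[-i]
    },
    "interpreter" = {
      sc$interpreter$version <- paste0(sc$interpreter$version, ".1")
    },
    "system" = {
      sc$system$os_release <- paste0(sc$system$os_release, "-updated")
    },
    "search-path" = {
      sc$search_path$entries[[2]] <-
        paste0(sc$search_path$entries[[2]], "-alt")
    },
    "user" = {
      sc$user$effective_user <- "2000(otheruser)"
    },
    "program" = {
      sc$program$checksum <- ri_rand_hex()
    },
    "args" = {
      sc$program$argv <- c(sc$program$argv, "--rerun")
      sc$program$arg_count <- length(sc$program$argv)
    },
    "exit-status" = {
      sc$window$exit_status <- if (identical(sc$window$exit_status, 0L)) {
        1L
      } else {
        0L
      }
    },
    "extra" = {
      sc$extra <- append(sc$extra,
                         list(log_record("NOTE", "injected extra record")))
    },
    stop("unknown perturbation category: ", cat_)
  )
  sc
}

## expected diff entries for a perturbation set: every category maps to
## exactly one diff entry of the same category
ri_expected_entry_categories <- function(perturbations) {
  sort(vapply(perturbations, function(p) p$category, character(1)),
       method = "radix")
}

#' Generate a deterministic log-document fixture
#'
#' Produces a pseudo-random but realistic log document from a
#' [fixture_spec()], and -- when the spec lists perturbations -- a second
#' document derived by applying exactly those perturbations. The derived
#' document always gets a fresh execution window (start/end/elapsed), which
#' is what two honest runs of the same program look like; under the default
#' diff ignore set this alone produces no differences. The host RNG state
#' is saved and restored, so fixture generation is invisible to the
#' caller's random streams.
#'
#' @param spec A `runinfo_fixture_spec`.
#' @param pair Derive the second document even with zero perturbations
#'   (it then differs from the first only in its execution window).
#' @return List with elements `a` (document), `b` (perturbed document or
#'   `NULL`), and `expected_categories` (sorted categories of the diff
#'   entries the injected perturbations must produce).
#' @export
generate_fixture <- function(spec, pair = length(spec$perturbations) > 0L) {
  stopifnot(inherits(spec, "runinfo_fixture_spec"))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  }, add = TRUE)
  set.seed(spec$seed)

  scene <- ri_fixture_scene(spec)
  doc_a <- ri_scene_document(scene)
  doc_b <- NULL
  if (isTRUE(pair)) {
    sc2 <- scene
    ## a second run always has its own execution window
    shift <- sample(60:86400, 1)
    sc2$window <- finalize_window(
      scene$window$start + shift,
      scene$window$start + shift + round(stats::runif(1, 1, 5000), 3),
      scene$window$exit_status
    )
    ## unnamed module perturbations draw distinct targets, so the injected
    ## set and the resulting diff entries correspond one-to-one
    perts <- spec$perturbations
    mod_cats <- c("module-version", "module-checksum", "module-removed")
    avail <- vapply(sc2$modules, function(m) m$name, character(1))
    for (j in seq_along(perts)) {
      if (perts[[j]]$category %in% mod_cats && is.null(perts[[j]]$name)) {
        if (length(avail) == 0L) {
          stop("cannot perturb modules of a fixture with n_modules = 0")
        }
        pick <- sample(seq_along(avail), 1)
        perts[[j]]$name <- avail[[pick]]
        avail <- avail[-pick]
      }
    }
    for (p in perts) {
      sc2 <- ri_apply_perturbation(sc2, p)
    }
    doc_b <- ri_scene_document(sc2)
  }
  list(a = doc_a, b = doc_b,
       expected_categories = ri_expected_entry_categories(spec$perturbations))
}
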