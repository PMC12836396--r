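#' Inter-laboratory synchronisation
#'
#' A minimal handshake protocol aligns the paradigm start across sites: each
#' laboratory's client connects to a host server and announces itself with a
#' single ASCII line `HELLO <site_id>`; once the host has accepted the
#' expected number of clients it broadcasts the line `START <epoch_s>` to
#' all of them and closes the connections (no in-task messaging). Each side
#' logs wall-clock times for six event classes: `code_run`, `connected`,
#' `trigger_received`, `experiment_start`, `block_start` (one per paradigm
#' block) and `experiment_end`.
#'
#' @name lab_sync
NULL

sync_now <- function() round(as.numeric(Sys.time()), 6)

sync_record <- function(site_id, event, wall_clock = sync_now(),
                        detail = "") {
  tibble(site_id = site_id, event = event,
         wall_clock = wall_clock, detail = detail)
}

#' Write / read a synchronisation log
#'
#' One record per line, `ISO8601<TAB>site_id<TAB>event<TAB>detail`, with
#' microsecond timestamps in UTC. Reading a written log reproduces the
#' original tibble (wall clocks to 1e-6 s).
#'
#' @param log sync-log tibble (`site_id`, `event`, `wall_clock`, `detail`).
#' @param path file path.
#' @return `write_sync_log` the path invisibly; `read_sync_log` the tibble.
#' @export
write_sync_log <- function(log, path) {
  stamp <- format(.POSIXct(log$wall_clock, tz = "UTC"),
                  "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")
  lines <- paste(stamp, log$site_id, log$event, log$detail, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sync_log
#' @export
read_sync_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble(site_id = character(), event = character(),
                  wall_clock = double(), detail = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    site_id = vapply(parts, `[`, "", 2),
    event = vapply(parts, `[`, "", 3),
    wall_clock = round(as.numeric(as.POSIXct(
      vapply(parts, `[`, "", 1), format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")), 6),
    detail = vapply(parts, function(p) if (length(p) >= 4) p[4] else "", "")
  )
}

sync_events <- c("code_run", "connected", "trigger_received",
                 "experiment_start", "block_start", "experiment_end")

#' Run the handshake host
#'
#' Accepts exactly `n_clients` connections, then broadcasts the start
#' trigger to all of them and closes the connections. If the accept loop
#' times out before all clients have connected, no trigger is sent and the
#' abort is logged.
#'
#' @param port TCP port to listen on.
#' @param n_clients number of expected clients.
#' @param timeout accept timeout in s (per client).
#' @param log_path optional path for the server-side log.
#' @return A list: `triggered` (logical), `n_connected`, `trigger_time`
#'   (epoch s or NA), `sites` (announced site ids), `log` (tibble).
#' @export
run_host <- function(port, n_clients = 2, timeout = 10, log_path = NULL) {
  log <- sync_record("host", "code_run")
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  cons <- list(); sites <- character()
  for (i in seq_len(n_clients)) {
    con <- tryCatch(
      suppressWarnings(socketAccept(srv, blocking = TRUE, timeout = timeout)),
      error = function(e) NULL)
    ok <- !is.null(con) && tryCatch(isOpen(con), error = function(e) FALSE)
    if (ok) {
      hello <- tryCatch(readLines(con, n = 1), error = function(e) character())
      if (length(hello) == 1 && startsWith(hello, "HELLO")) {
        cons[[length(cons) + 1L]] <- con
        site <- sub("^HELLO\\s*", "", hello)
        sites <- c(sites, site)
        log <- bind_rows(log, sync_record("host", "connected", detail = site))
        next
      }
    }
    if (!is.null(con) && ok) close(con)
    # timeout or bad handshake: abort without triggering
    for (c2 in cons) close(c2)
    log <- bind_rows(log, sync_record("host", "experiment_end",
                                      detail = "abort: timeout"))
    if (!is.null(log_path)) write_sync_log(log, log_path)
    return(list(triggered = FALSE, n_connected = length(cons),
                trigger_time = NA_real_, sites = sites, log = log))
  }
  trigger_time <- sync_now()
  for (con in cons) {
    writeLines(sprintf("START %.6f", trigger_time), con)
    flush(con)
  }
  log <- bind_rows(log, sync_record("host", "experiment_start",
                                    wall_clock = trigger_time,
                                    detail = "trigger broadcast"))
  for (con in cons) close(con)
  log <- bind_rows(log, sync_record("host", "experiment_end"))
  if (!is.null(log_path)) write_sync_log(log, log_path)
  list(triggered = TRUE, n_connected = length(cons),
       trigger_time = trigger_time, sites = sites, log = log)
}

#' Run a handshake client
#'
#' Connects to the host (with retries and exponential backoff), announces
#' its site, blocks until the start trigger arrives, then steps through the
#' paradigm, logging every block start, and logs the experiment end. When
#' no trigger arrives within the timeout the experiment never starts and
#' the partial log is flagged with an `abort` detail.
#'
#' @param host host name or IP.
#' @param port TCP port.
#' @param site_id this laboratory's label.
#' @param paradigm block table whose rows produce `block_start` records.
#' @param paradigm_hook optional function called once per block (row).
#' @param log_path optional path for the client log file.
#' @param timeout trigger-wait timeout in s.
#' @param retries connection attempts (exponential backoff).
#' @param realtime sleep through real block durations (`FALSE` for
#'   loopback validation, which logs blocks back-to-back).
#' @return The sync-log tibble (invisibly written to `log_path` if given).
#' @export
run_client <- function(host, port, site_id, paradigm,
                       paradigm_hook = NULL, log_path = NULL, timeout = 10,
                       retries = 5, realtime = FALSE) {
  log <- sync_record(site_id, "code_run")
  con <- NULL
  for (k in seq_len(retries)) {
    con <- tryCatch(
      socketConnection(host, port, blocking = TRUE, open = "r+",
                       timeout = timeout),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (!is.null(con)) break
    Sys.sleep(0.05 * 2^(k - 1))
  }
  if (is.null(con)) abort(sprintf("could not connect to %s:%d after %d attempts.",
                                  host, port, retries))
  on.exit(tryCatch(close(con), error = function(e) NULL), add = TRUE)
  log <- bind_rows(log, sync_record(site_id, "connected"))
  writeLines(paste("HELLO", site_id), con)
  flush(con)
  msg <- tryCatch(readLines(con, n = 1), error = function(e) character())
  if (length(msg) != 1 || !startsWith(msg, "START")) {
    log <- bind_rows(log, sync_record(site_id, "experiment_end",
                                      detail = "abort: no trigger"))
    if (!is.null(log_path)) write_sync_log(log, log_path)
    return(invisible(log))
  }
  log <- bind_rows(log, sync_record(site_id, "trigger_received",
                                    detail = sub("^START\\s*", "", msg)))
  t0 <- sync_now()
  log <- bind_rows(log, sync_record(site_id, "experiment_start",
                                    wall_clock = t0))
  for (i in seq_len(nrow(paradigm))) {
    if (realtime && i > 1) {
      Sys.sleep(max(0, paradigm$onset[i] - (sync_now() - t0)))
    }
    if (!is.null(paradigm_hook)) paradigm_hook(paradigm[i, ])
    log <- bind_rows(log, sync_record(
      site_id, "block_start",
      detail = sprintf("%s@%gs", paradigm$condition[i], paradigm$onset[i])))
  }
  log <- bind_rows(log, sync_record(site_id, "experiment_end"))
  if (!is.null(log_path)) write_sync_log(log, log_path)
  invisible(log)
}

#' Estimate the inter-site clock offset from two logs
#'
#' Matches event records across the two logs (by event class and occurrence
#' order) and reports, per matched event, the clock-difference residual
#' `lag = (tA - tB) - ground_truth_offset`. The mean lag over connection
#' events estimates any unaccounted offset; residual lags near zero confirm
#' synchronised delivery.
#'
#' @param log_a,log_b sync-log tibbles from the two sites.
#' @param ground_truth_offset known clock difference `tA - tB` in s.
#' @return A list of class `sync_offset`: `per_event` tibble (`event`,
#'   `occurrence`, `t_a`, `t_b`, `lag`), `summary` tibble (mean/sd/max
#'   absolute lag), `unmatched` (events present in only one log).
#' @export
estimate_offset <- function(log_a, log_b, ground_truth_offset = 0) {
  index_events <- function(log) {
    log %>% group_by(.data$event) %>%
      mutate(occurrence = seq_len(n())) %>% ungroup()
  }
  a <- index_events(log_a); b <- index_events(log_b)
  joined <- dplyr::inner_join(
    a %>% select("event", "occurrence", t_a = "wall_clock"),
    b %>% select("event", "occurrence", t_b = "wall_clock"),
    by = c("event", "occurrence")
  ) %>%
    mutate(lag = (.data$t_a - .data$t_b) - ground_truth_offset)
  unmatched <- dplyr::anti_join(
    bind_rows(a %>% mutate(side = "a"), b %>% mutate(side = "b")) %>%
      select("side", "event", "occurrence"),
    joined %>% select("event", "occurrence"),
    by = c("event", "occurrence")
  )
  structure(list(
    per_event = joined,
    summary = tibble(n = nrow(joined),
                     mean_lag = mean(joined$lag),
                     sd_lag = sd(joined$lag),
                     max_abs_lag = max(abs(joined$lag))),
    unmatched = unmatched
  ), class = "sync_offset")
}

#' @export
glance.sync_offset <- function(x, ...) x$summary

#' Find a free TCP port
#'
#' @param from,to port range searched.
#' @param seed seed controlling the search order.
#' @return An open port number.
#' @export
free_port <- function(from = 20000, to = 40000, seed = NULL) {
  ports <- if (is.null(seed)) sample(from:to, 50) else
    with_seed(seed, sample(from:to, 50))
  for (p in ports) {
    ok <- tryCatch({
      s <- serverSocket(p); close(s); TRUE
    }, error = function(e) FALSE)
    if (ok) return(p)
  }
  abort("no free port found.")
}

#' Loopback validation session
#'
#' Spawns `n_clients` client subprocesses on 127.0.0.1, runs the host
#' in-process, and collects every side's log. This is the validation
#' harness for the synchronisation protocol: causality (no client starts
#' before the broadcast) and log completeness are asserted on its output.
#'
#' @param paradigm block table for the clients.
#' @param n_clients number of clients.
#' @param port TCP port (default: a free one).
#' @param timeout accept/trigger timeout in s.
#' @return A list: `host` (see [run_host()]), `client_logs` (list of
#'   tibbles, one per client).
#' @export
sync_loopback_session <- function(paradigm, n_clients = 2,
                                  port = free_port(), timeout = 30) {
  dir <- tempfile("sync"); dir.create(dir)
  events_path <- file.path(dir, "events.tsv")
  readr::write_tsv(as_tibble(paradigm)[, c("onset", "duration", "condition")],
                   events_path)
  log_paths <- file.path(dir, sprintf("client%d.log", seq_len(n_clients)))
  scripts <- vapply(seq_len(n_clients), function(i) {
    sp <- file.path(dir, sprintf("client%d.R", i))
    writeLines(sprintf(
      'suppressMessages(library(fnirsdyad))
events <- readr::read_tsv("%s", show_col_types = FALSE)
run_client("127.0.0.1", %d, site_id = "site%d", paradigm = events,
           log_path = "%s", timeout = %d, retries = 8)',
      events_path, port, i, log_paths[i], timeout), sp)
    sp
  }, "")
  rbin <- file.path(R.home("bin"), "Rscript")
  for (sp in scripts) {
    system2(rbin, c("--vanilla", shQuote(sp)), wait = FALSE,
            stdout = FALSE, stderr = FALSE)
  }
  host <- run_host(port, n_clients = n_clients, timeout = timeout,
                   log_path = file.path(dir, "host.log"))
  deadline <- Sys.time() + timeout
  while (!all(file.exists(log_paths)) && Sys.time() < deadline) {
    Sys.sleep(0.1)
  }
  Sys.sleep(0.2)  # let clients finish writing
  client_logs <- lapply(log_paths, function(p) {
    if (file.exists(p)) read_sync_log(p) else NULL
  })
  list(host = host, client_logs = client_logs, dir = dir)
}
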