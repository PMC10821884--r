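# Shared fixture builders for the suite. Everything is generated in code;
# nothing is read from disk outside the temporary stores created here.

local_store <- function(env = parent.frame()) {
  dir <- tempfile("store")
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  store_open(dir)
}

# A store preloaded with the 3-reaction chain model.
local_toy_store <- function(env = parent.frame()) {
  store <- local_store(env)
  toy <- generate_toy_model("chain", 3)
  register_model(store, toy$sbml, "toy3", source_db = "fixture")
  store
}

ko <- function(target) mod_entry(target, "knockout")
sb <- function(target, lo, hi) mod_entry(target, "set_bounds", lo, hi)

entry_sig <- function(e)
  paste(e$target, e$operation,
        if (is.null(e$lower)) "" else format(e$lower),
        if (is.null(e$upper)) "" else format(e$upper))

store_mod <- function(store, name, root, entries, parent = NULL,
                      author = "tester", date = "2024-01-01T00:00:00Z") {
  mf <- modification_file(name, author, root, entries, parent = parent,
                          date = date)
  put_modification_file(store, mf)
  mf
}
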