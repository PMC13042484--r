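# H5AD interchange goes through the Python `anndata` package (a subprocess;
# no R HDF5 binding is required). The bridge materialises a temporary
# delimited layout on either side of the conversion.

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    stop("h5ad support requires a `python` interpreter with the anndata ",
         "package on PATH", call. = FALSE)
  p
}

run_python <- function(code, args = character()) {
  script <- tempfile(fileext = ".py")
  on.exit(unlink(script))
  writeLines(code, script)
  out <- suppressWarnings(system2(python_bin(), c(script, args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python conversion failed:\n", paste(out, collapse = "\n"),
         call. = FALSE)
  invisible(out)
}

load_h5ad <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tmp <- tempfile("h5ad_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  run_python(c(
    "import sys, numpy as np, anndata as ad, scipy.sparse as sp",
    "src, out = sys.argv[1], sys.argv[2]",
    "a = ad.read_h5ad(src)",
    "X = a.X.toarray() if sp.issparse(a.X) else np.asarray(a.X)",
    "if 'spatial' not in a.obsm:",
    "    sys.exit('coords-missing: no obsm[spatial] in h5ad')",
    "S = np.asarray(a.obsm['spatial'])[:, :2]",
    "import pandas as pd",
    "df = pd.DataFrame(X, index=a.obs_names, columns=a.var_names)",
    "df.to_csv(out + '/counts.tsv', sep='\\t')",
    "pd.DataFrame({'spot_id': a.obs_names, 'x': S[:,0], 'y': S[:,1]}).to_csv(",
    "    out + '/coords.tsv', sep='\\t', index=False)"
  ), c(path, tmp))
  load_delimited(tmp)
}

write_h5ad <- function(ds, path) {
  tmp <- tempfile("h5ad_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  write_dataset(ds, tmp, format = "delimited")
  run_python(c(
    "import sys, numpy as np, pandas as pd, anndata as ad",
    "src, out = sys.argv[1], sys.argv[2]",
    "df = pd.read_csv(src + '/counts.tsv', sep='\\t', index_col=0)",
    "pos = pd.read_csv(src + '/coords.tsv', sep='\\t')",
    "a = ad.AnnData(X=df.values.astype('float32'),",
    "               obs=pd.DataFrame(index=df.index.astype(str)),",
    "               var=pd.DataFrame(index=df.columns.astype(str)))",
    "a.obsm['spatial'] = pos[['x', 'y']].values.astype('float64')",
    "a.write_h5ad(out)"
  ), c(tmp, path))
  invisible(path)
}
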