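#include <string.h>
#include <R.h>
#include <Rinternals.h>
#include <zlib.h>

/* RFC 1950 zlib stream at a caller-chosen compression level.
   base R's memCompress() offers no level control, which this format needs. */
SEXP c_deflate(SEXP data, SEXP level)
{
    R_xlen_t n = XLENGTH(data);
    int lev = asInteger(level);
    if (lev < 0 || lev > 9)
        error("deflate level must be in 0..9 (got %d)", lev);
    uLong bound = compressBound((uLong) n);
    SEXP buf = PROTECT(allocVector(RAWSXP, (R_xlen_t) bound));
    uLongf dest_len = bound;
    int ret = compress2(RAW(buf), &dest_len, RAW(data), (uLong) n, lev);
    if (ret != Z_OK)
        error("zlib compress2 failed (code %d)", ret);
    SEXP out = PROTECT(allocVector(RAWSXP, (R_xlen_t) dest_len));
    memcpy(RAW(out), RAW(buf), dest_len);
    UNPROTECT(2);
    return out;
}

SEXP c_inflate(SEXP data)
{
    R_xlen_t n = XLENGTH(data);
    uLongf cap = n > 16 ? (uLongf) n * 4 : 64;
    for (int tries = 0; tries < 12; tries++) {
        SEXP buf = PROTECT(allocVector(RAWSXP, (R_xlen_t) cap));
        uLongf dest_len = cap;
        int ret = uncompress(RAW(buf), &dest_len, RAW(data), (uLong) n);
        if (ret == Z_OK) {
            SEXP out = PROTECT(allocVector(RAWSXP, (R_xlen_t) dest_len));
            memcpy(RAW(out), RAW(buf), dest_len);
            UNPROTECT(2);
            return out;
        }
        UNPROTECT(1);
        if (ret == Z_BUF_ERROR) { cap *= 4; continue; }
        error("not a valid zlib stream (zlib code %d)", ret);
    }
    error("zlib stream expands beyond supported size");
    return R_NilValue; /* unreached */
}

static const R_CallMethodDef call_entries[] = {
    {"c_deflate", (DL_FUNC) &c_deflate, 2},
    {"c_inflate", (DL_FUNC) &c_inflate, 1},
    {NULL, NULL, 0}
};

void R_init_airdlite(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
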