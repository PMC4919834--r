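#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP ri_once(void);
extern SEXP ri_once_reset(void);
extern SEXP ri_install_handlers(SEXP, SEXP);
extern SEXP ri_signal_numbers(void);
extern SEXP ri_libc_version(void);
extern SEXP ri_user_info(void);

static const R_CallMethodDef call_entries[] = {
    { "ri_once",             (DL_FUNC) &ri_once,             0 },
    { "ri_once_reset",       (DL_FUNC) &ri_once_reset,       0 },
    { "ri_install_handlers", (DL_FUNC) &ri_install_handlers, 2 },
    { "ri_signal_numbers",   (DL_FUNC) &ri_signal_numbers,   0 },
    { "ri_libc_version",     (DL_FUNC) &ri_libc_version,     0 },
    { "ri_user_info",        (DL_FUNC) &ri_user_info,        0 },
    { NULL, NULL, 0 }
};

void R_init_runinfo(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
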