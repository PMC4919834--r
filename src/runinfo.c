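/* Low-level process introspection and signal plumbing.
 *
 * The emission-on-signal path runs R code from inside a signal handler.
 * That is only attempted for terminating signals: after the R callback
 * returns the handler restores the default disposition and re-raises, so
 * the process always dies with the conventional signal status and the
 * handler never resumes interrupted R code.
 */
#include <R.h>
#include <Rinternals.h>

#ifndef _WIN32
#include <signal.h>
#include <string.h>
#include <unistd.h>
#include <sys/types.h>
#include <pwd.h>
#include <grp.h>
#endif

#define RI_MAXSIG 64

#ifndef _WIN32
static struct sigaction ri_old[RI_MAXSIG];
static int ri_have_old[RI_MAXSIG];
#endif
static SEXP ri_callback = NULL;

/* once-only emission guard; sig_atomic_t so the flag is coherent when a
 * handler interrupts the normal-exit emission path */
static volatile sig_atomic_t ri_emitted_flag = 0;
static volatile sig_atomic_t ri_in_handler = 0;

SEXP ri_once(void)
{
    if (ri_emitted_flag)
        return Rf_ScalarLogical(0);
    ri_emitted_flag = 1;
    return Rf_ScalarLogical(1);
}

SEXP ri_once_reset(void)
{
    ri_emitted_flag = 0;
    ri_in_handler = 0;
    return R_NilValue;
}

#ifndef _WIN32
static void ri_handler(int sig)
{
    if (!ri_in_handler) {
        ri_in_handler = 1;
        if (ri_callback != NULL) {
            int err = 0;
            SEXP call = PROTECT(Rf_lang2(ri_callback, Rf_ScalarInteger(sig)));
            R_tryEval(call, R_GlobalEnv, &err);
            UNPROTECT(1);
        }
        /* chain a plain handler the host had installed before activation */
        if (sig > 0 && sig < RI_MAXSIG && ri_have_old[sig]) {
            void (*h)(int) = ri_old[sig].sa_handler;
            if (h != SIG_DFL && h != SIG_IGN &&
                !(ri_old[sig].sa_flags & SA_SIGINFO))
                h(sig);
        }
    }
    /* terminate with the platform-conventional signal status */
    signal(sig, SIG_DFL);
    sigset_t ss;
    sigemptyset(&ss);
    sigaddset(&ss, sig);
    sigprocmask(SIG_UNBLOCK, &ss, NULL);
    raise(sig);
}
#endif

/* install handlers for the given signal numbers; returns a logical vector
 * marking which could be trapped (untrappable ones are skipped silently) */
SEXP ri_install_handlers(SEXP sigs, SEXP fn)
{
    int n = LENGTH(sigs);
    SEXP ok = PROTECT(Rf_allocVector(LGLSXP, n));
    for (int i = 0; i < n; i++)
        LOGICAL(ok)[i] = FALSE;
#ifndef _WIN32
    if (!Rf_isFunction(fn))
        Rf_error("callback must be a function");
    if (ri_callback != NULL)
        R_ReleaseObject(ri_callback);
    ri_callback = fn;
    R_PreserveObject(ri_callback);
    for (int i = 0; i < n; i++) {
        int s = INTEGER(sigs)[i];
        if (s <= 0 || s >= RI_MAXSIG)
            continue;
        struct sigaction sa, prev;
        memset(&sa, 0, sizeof sa);
        sa.sa_handler = ri_handler;
        sigfillset(&sa.sa_mask); /* defer other signals during emission */
        if (sigaction(s, &sa, &prev) == 0) {
            ri_old[s] = prev;
            ri_have_old[s] = 1;
            LOGICAL(ok)[i] = TRUE;
        }
    }
#endif
    UNPROTECT(1);
    return ok;
}

/* numbers for the catchable termination signals, named on the R side */
SEXP ri_signal_numbers(void)
{
#ifndef _WIN32
    SEXP v = PROTECT(Rf_allocVector(INTSXP, 4));
    INTEGER(v)[0] = SIGHUP;
    INTEGER(v)[1] = SIGINT;
    INTEGER(v)[2] = SIGQUIT;
    INTEGER(v)[3] = SIGTERM;
    UNPROTECT(1);
    return v;
#else
    return R_NilValue;
#endif
}

SEXP ri_libc_version(void)
{
#if defined(_CS_GNU_LIBC_VERSION)
    char buf[256];
    size_t n = confstr(_CS_GNU_LIBC_VERSION, buf, sizeof buf);
    if (n > 0 && n <= sizeof buf)
        return Rf_mkString(buf);
#endif
    return R_NilValue;
}

#ifndef _WIN32
static SEXP ri_chr1(const char *s)
{
    return Rf_mkString(s ? s : "UNKNOWN");
}
#endif

/* real/effective uid+gid, user/group names, supplementary groups */
SEXP ri_user_info(void)
{
#ifdef _WIN32
    return R_NilValue;
#else
    uid_t ru = getuid(), eu = geteuid();
    gid_t rg = getgid(), eg = getegid();
    struct passwd *rpw = getpwuid(ru), *epw = getpwuid(eu);
    struct group *rgr = getgrgid(rg), *egr = getgrgid(eg);

    int ng = getgroups(0, NULL);
    if (ng < 0)
        ng = 0;
    gid_t gids[256];
    if (ng > 256)
        ng = 256;
    if (ng > 0)
        ng = getgroups(ng, gids);
    if (ng < 0)
        ng = 0;

    const char *nms[] = { "ruid",   "euid",   "rgid",   "egid",
                          "runame", "euname", "rgname", "egname",
                          "groups", "group_names" };
    SEXP out = PROTECT(Rf_allocVector(VECSXP, 10));
    SEXP nm = PROTECT(Rf_allocVector(STRSXP, 10));
    for (int i = 0; i < 10; i++)
        SET_STRING_ELT(nm, i, Rf_mkChar(nms[i]));
    Rf_setAttrib(out, R_NamesSymbol, nm);

    SET_VECTOR_ELT(out, 0, Rf_ScalarInteger((int) ru));
    SET_VECTOR_ELT(out, 1, Rf_ScalarInteger((int) eu));
    SET_VECTOR_ELT(out, 2, Rf_ScalarInteger((int) rg));
    SET_VECTOR_ELT(out, 3, Rf_ScalarInteger((int) eg));
    SET_VECTOR_ELT(out, 4, ri_chr1(rpw ? rpw->pw_name : NULL));
    SET_VECTOR_ELT(out, 5, ri_chr1(epw ? epw->pw_name : NULL));
    SET_VECTOR_ELT(out, 6, ri_chr1(rgr ? rgr->gr_name : NULL));
    SET_VECTOR_ELT(out, 7, ri_chr1(egr ? egr->gr_name : NULL));

    SEXP gv = PROTECT(Rf_allocVector(INTSXP, ng));
    SEXP gn = PROTECT(Rf_allocVector(STRSXP, ng));
    for (int i = 0; i < ng; i++) {
        INTEGER(gv)[i] = (int) gids[i];
        struct group *gr = getgrgid(gids[i]);
        SET_STRING_ELT(gn, i, Rf_mkChar(gr ? gr->gr_name : "UNKNOWN"));
    }
    SET_VECTOR_ELT(out, 8, gv);
    SET_VECTOR_ELT(out, 9, gn);
    UNPROTECT(4);
    return out;
#endif
}
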