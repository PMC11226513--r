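#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* The model entry points are resolved dynamically by name through
 * deSolve (func = "...", dllname = "debatch"), so dynamic symbol
 * lookup stays enabled. */
void R_init_debatch(DllInfo *dll)
{
  R_registerRoutines(dll, NULL, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
}
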