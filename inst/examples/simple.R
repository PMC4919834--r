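# Trivial instrumented program: one activation line, one line of output.
# At exit the logger announces where the provenance log was written.
runinfo::activate()
cat("Hello, world!\n")
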