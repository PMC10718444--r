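# Build with the system compiler: the conda-provided cross toolchain links
# against a sysroot glibc newer than the one the dynamic loader resolves,
# producing objects that cannot be loaded.
override CXX = g++
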