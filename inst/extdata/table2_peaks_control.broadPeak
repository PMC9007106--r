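track name=control description="no peaks called"
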