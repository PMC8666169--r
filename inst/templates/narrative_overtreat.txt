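For every person correctly identified as needing attention, another
{overtreat} will be flagged unnecessarily.
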