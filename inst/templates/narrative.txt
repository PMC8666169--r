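Of {population} people, {events} will have the event and {non_events} will not.
{at_risk} are classified as at risk, of whom {tp} will have the event; the rule
correctly identifies {tp} of {events} people who will go on to have the event.
Of the {not_at_risk} classified as not at risk, {fn} will have the event.
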