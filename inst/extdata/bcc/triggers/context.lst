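# ConText trigger lexicon: minorType = category:direction
no	context	negation:forward
not	context	negation:forward
without	context	negation:forward
free of	context	negation:forward
negative for	context	negation:forward
absent	context	negation:backward
not identified	context	negation:backward
not seen	context	negation:backward
confined to	context	affirmation:forward
clear of	context	affirmation:forward
well away from	context	affirmation:forward
completely excised	context	affirmation:backward
no increase	context	pseudo
no change	context	pseudo
but	context	termination
however	context	termination
apart from	context	termination
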