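# Default exclusion rules for the Mpala olive-baboon Movebank release.
# Format: individual_id,reason   (all days)
#     or: individual_id,YYYY-MM-DD,reason   (that day only)
2459,no corresponding demographic data
2452,2012-08-14,GPS readings clearly in error; device recorded only 9.5 h
2432,2012-08-05,track recorded only 1.55 h
2450,2012-08-05,track recorded only 4.57 h
2433,2012-08-06,track recorded only 7.1 h
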