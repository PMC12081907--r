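state,population
Pennsylvania,13002700
New York,20201249
Massachusetts,7029917
New Jersey,9288994
Connecticut,3605944
Illinois,12812508
Ohio,11799448
Michigan,10077331
Minnesota,5706494
Missouri,6154913
Indiana,6785528
Georgia,10711908
Texas,29145505
Florida,21538187
Tennessee,6910840
North Carolina,10439388
Louisiana,4657757
California,39538223
Washington,7705281
Oregon,4237256
Colorado,5773714
Arizona,7151502
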