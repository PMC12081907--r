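community,city,state,region
philadelphia,Philadelphia,Pennsylvania,Northeast
pittsburgh,Pittsburgh,Pennsylvania,Northeast
nyc,New York,New York,Northeast
boston,Boston,Massachusetts,Northeast
newjersey,,New Jersey,Northeast
connecticut,,Connecticut,Northeast
chicago,Chicago,Illinois,Midwest
columbus,Columbus,Ohio,Midwest
detroit,Detroit,Michigan,Midwest
minneapolis,Minneapolis,Minnesota,Midwest
stlouis,St. Louis,Missouri,Midwest
indianapolis,Indianapolis,Indiana,Midwest
atlanta,Atlanta,Georgia,South
houston,Houston,Texas,South
dallas,Dallas,Texas,South
miami,Miami,Florida,South
nashville,Nashville,Tennessee,South
charlotte,Charlotte,North Carolina,South
neworleans,New Orleans,Louisiana,South
losangeles,Los Angeles,California,West
sanfrancisco,San Francisco,California,West
seattle,Seattle,Washington,West
portland,Portland,Oregon,West
denver,Denver,Colorado,West
phoenix,Phoenix,Arizona,West
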